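# On-disk sharded graph store.
#
# Each undirected edge is materialized as two directed arcs; the vertex range
# [0, n) is split into K contiguous intervals and each interval owns one shard
# file holding every arc whose destination falls inside the interval, sorted
# by source vertex (ties by destination). Records are fixed-size little-endian
# (src: uint32, dst: uint32, w: float64 = 16 bytes) so offsets are arithmetic.
# A JSON manifest describes the layout and carries per-file md5 checksums and,
# per shard, the cumulative record counts at each interval boundary; those
# cumulative counts are what lets the parallel-sliding-windows traversal seek
# each shard's out-arc window with a single non-sequential read.

SHARD_RECORD_BYTES <- 16L
SHARD_FORMAT_VERSION <- 1L

#' Split a graph into interval shards on disk
#'
#' Partitions vertex ids into `K` contiguous intervals balanced by in-arc
#' count (greedy: an interval grows until it holds at least `total_arcs / K`
#' arcs, leaving at least one vertex per remaining interval), writes one
#' binary shard of source-sorted in-arcs per interval, persists the
#' accession/id map as TSV and a JSON manifest with checksums.
#'
#' @param graph a [weighted_graph()].
#' @param K number of vertex intervals (1 <= K <= n).
#' @param dir output directory (created if missing).
#' @param name basename for the on-disk files.
#' @param arc_budget optional cap on arcs per shard; when supplied it
#'   overrides `total_arcs / K` as the greedy growth target.
#' @return a `sharded_graph` handle (also recoverable later with
#'   [open_sharded_graph()]).
#' @export
build_shards <- function(graph, K, dir = tempfile("shards"), name = "graph",
                         arc_budget = NULL) {
  stopifnot(inherits(graph, "weighted_graph"))
  K <- as.integer(K)
  n <- graph$n
  if (n == 0L) stop("cannot shard an empty graph")
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of vertices (", n, ")")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  e <- graph$edges
  arcs_src <- c(e$src, e$dst)
  arcs_dst <- c(e$dst, e$src)
  arcs_w <- c(e$weight, e$weight)
  m <- length(arcs_src)

  # interval boundaries: balance by in-arc count
  in_counts <- tabulate(arcs_dst + 1L, nbins = n)
  target <- if (is.null(arc_budget)) max(1, ceiling(m / K)) else arc_budget
  bounds <- integer(K + 1L)  # 0-based starts; bounds[K+1] = n
  v <- 0L
  for (k in seq_len(K)) {
    bounds[k] <- v
    acc <- 0L
    remaining_intervals <- K - k
    while (v < n - remaining_intervals &&
           (acc < target || v == bounds[k])) {
      acc <- acc + in_counts[v + 1L]
      v <- v + 1L
      if (acc >= target) break
    }
    if (v == bounds[k]) v <- v + 1L  # always take at least one vertex
  }
  bounds[K + 1L] <- n

  interval_of <- findInterval(arcs_dst, bounds[-(K + 1L)])  # 1..K
  shard_files <- character(K)
  records <- integer(K)
  src_index <- vector("list", K)
  for (k in seq_len(K)) {
    sel <- which(interval_of == k)
    ord <- sel[order(arcs_src[sel], arcs_dst[sel])]
    fn <- sprintf("%s.shard.%d.bin", name, k - 1L)
    con <- file(file.path(dir, fn), "wb")
    if (length(ord)) {
      rec <- raw(SHARD_RECORD_BYTES * length(ord))
      rec_mat <- matrix(rec, nrow = SHARD_RECORD_BYTES)
      rec_mat[1:4, ] <- matrix(writeBin(as.integer(arcs_src[ord]), raw(),
                                        size = 4L, endian = "little"), nrow = 4)
      rec_mat[5:8, ] <- matrix(writeBin(as.integer(arcs_dst[ord]), raw(),
                                        size = 4L, endian = "little"), nrow = 4)
      rec_mat[9:16, ] <- matrix(writeBin(arcs_w[ord], raw(),
                                         size = 8L, endian = "little"), nrow = 8)
      writeBin(as.vector(rec_mat), con)
    }
    close(con)
    shard_files[k] <- fn
    records[k] <- length(ord)
    # cumulative count of records with src < each interval boundary
    src_index[[k]] <- findInterval(bounds - 0.5, sort(arcs_src[ord]))
  }

  idmap_file <- paste0(name, ".idmap.tsv")
  utils::write.table(data.frame(accession = graph$id_map,
                                id = seq_len(n) - 1L),
                     file.path(dir, idmap_file), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  manifest <- list(
    format_version = SHARD_FORMAT_VERSION,
    endianness = "little",
    n = n,
    arc_count = m,
    undirected_edge_count = nrow(e),
    K = K,
    interval_starts = bounds[seq_len(K)],
    interval_ends = bounds[-1L],
    idmap_file = idmap_file,
    shards = lapply(seq_len(K), function(k) list(
      file = shard_files[k],
      records = records[k],
      checksum = unname(tools::md5sum(file.path(dir, shard_files[k]))),
      src_cumulative = src_index[[k]]
    ))
  )
  manifest_path <- file.path(dir, paste0(name, ".manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  open_sharded_graph(manifest_path)
}

#' Open a sharded graph from its manifest
#'
#' @param manifest_path path to the `.manifest.json` written by
#'   [build_shards()].
#' @return a `sharded_graph` handle.
#' @export
open_sharded_graph <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  dir <- dirname(manifest_path)
  idmap <- utils::read.table(file.path(dir, man$idmap_file), sep = "\t",
                             stringsAsFactors = FALSE,
                             col.names = c("accession", "id"),
                             colClasses = c("character", "integer"))
  idmap <- idmap[order(idmap$id), , drop = FALSE]
  structure(list(dir = dir, manifest = man, id_map = idmap$accession,
                 n = man$n, K = man$K),
            class = "sharded_graph")
}

#' @export
print.sharded_graph <- function(x, ...) {
  cat(sprintf("sharded_graph: %d vertices, %d arcs, K=%d shards in %s\n",
              x$n, x$manifest$arc_count, x$K, x$dir))
  invisible(x)
}

verify_shard_checksums <- function(sharded) {
  for (sh in sharded$manifest$shards) {
    path <- file.path(sharded$dir, sh$file)
    if (!file.exists(path)) stop("missing shard file: ", path)
    if (unname(tools::md5sum(path)) != sh$checksum)
      stop("checksum mismatch for shard file: ", path)
  }
  invisible(TRUE)
}

parse_shard_records <- function(raw_bytes) {
  nrec <- length(raw_bytes) %/% SHARD_RECORD_BYTES
  if (nrec == 0L)
    return(list(src = integer(0), dst = integer(0), w = numeric(0)))
  mat <- matrix(raw_bytes, nrow = SHARD_RECORD_BYTES)
  list(
    src = readBin(as.vector(mat[1:4, , drop = FALSE]), "integer", n = nrec,
                  size = 4L, endian = "little"),
    dst = readBin(as.vector(mat[5:8, , drop = FALSE]), "integer", n = nrec,
                  size = 4L, endian = "little"),
    w = readBin(as.vector(mat[9:16, , drop = FALSE]), "double", n = nrec,
                size = 8L, endian = "little")
  )
}

#' Traverse a sharded graph with parallel sliding windows
#'
#' Processes intervals in order. For each interval its own shard (the
#' "memory shard") is loaded in full with one non-sequential read; the
#' out-arcs of the interval's vertices that live in every other shard are
#' obtained by seeking that shard's sliding window (at most one further
#' non-sequential read per shard). The visitor is invoked exactly once per
#' vertex per pass with the vertex's in-arcs.
#'
#' @param sharded a `sharded_graph`.
#' @param visitor `function(vid, in_src, in_w)` called for every vertex id
#'   in `[0, n)`; `in_src`/`in_w` are the source ids and weights of the
#'   vertex's in-arcs (possibly empty).
#' @param verify when `TRUE` (default) shard checksums are verified against
#'   the manifest before the pass.
#' @return list with `nonseq_reads` (total count for the pass, guaranteed
#'   `<= K^2`), `per_interval` read counts, `vertices_visited` and
#'   `out_arc_records` (number of out-arc window records scanned).
#' @export
sliding_window_pass <- function(sharded, visitor, verify = TRUE) {
  stopifnot(inherits(sharded, "sharded_graph"))
  if (verify) verify_shard_checksums(sharded)
  man <- sharded$manifest
  K <- man$K
  starts <- man$interval_starts
  ends <- man$interval_ends
  cons <- lapply(man$shards, function(sh)
    file(file.path(sharded$dir, sh$file), "rb"))
  on.exit(lapply(cons, close), add = TRUE)

  per_interval <- integer(K)
  out_arc_records <- 0L
  visited <- 0L
  for (i in seq_len(K)) {
    reads <- 0L
    # memory shard: full sequential load (one non-sequential positioning)
    nrec <- man$shards[[i]]$records
    if (nrec > 0L) {
      seek(cons[[i]], 0L)
      reads <- reads + 1L
      mem <- parse_shard_records(readBin(cons[[i]], "raw",
                                         n = nrec * SHARD_RECORD_BYTES))
    } else {
      mem <- list(src = integer(0), dst = integer(0), w = numeric(0))
    }
    # out-arc windows: arcs with src in this interval stored in other shards
    for (s in seq_len(K)) {
      if (s == i) next
      cum <- man$shards[[s]]$src_cumulative
      from <- cum[i]
      count <- cum[i + 1L] - cum[i]
      if (count > 0L) {
        seek(cons[[s]], from * SHARD_RECORD_BYTES)
        reads <- reads + 1L
        win <- readBin(cons[[s]], "raw", n = count * SHARD_RECORD_BYTES)
        out_arc_records <- out_arc_records + count
      }
    }
    per_interval[i] <- reads

    ids <- starts[i]:(ends[i] - 1L)
    groups <- split(seq_along(mem$dst),
                    factor(mem$dst, levels = ids))
    for (j in seq_along(ids)) {
      idx <- groups[[j]]
      visitor(ids[j], mem$src[idx], mem$w[idx])
      visited <- visited + 1L
    }
  }
  list(nonseq_reads = sum(per_interval), per_interval = per_interval,
       vertices_visited = visited, out_arc_records = out_arc_records)
}

#' Read every arc stored in a sharded graph
#'
#' Utility for verification and round-tripping: concatenates all shard
#' records into a single arc table.
#'
#' @param sharded a `sharded_graph`.
#' @return data frame with columns `src`, `dst`, `w` (directed arcs).
#' @export
read_all_arcs <- function(sharded) {
  parts <- lapply(sharded$manifest$shards, function(sh) {
    con <- file(file.path(sharded$dir, sh$file), "rb")
    on.exit(close(con))
    parse_shard_records(readBin(con, "raw",
                                n = sh$records * SHARD_RECORD_BYTES))
  })
  data.frame(src = unlist(lapply(parts, `[[`, "src")),
             dst = unlist(lapply(parts, `[[`, "dst")),
             w = unlist(lapply(parts, `[[`, "w")))
}
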