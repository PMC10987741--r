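# FASTA ingestion and the natural-vector cache. Reading goes through
# Biostrings (wrapped or single-line records, case-insensitive, IUPAC
# ambiguity codes tolerated). The cache stores one JSON document per
# (id, k) with the sparse vector entries sorted by k-mer, keyed by an MD5
# digest of the uppercased sequence so that edits invalidate exactly the
# records they touch.

#' Read a multi-FASTA file as sequence records
#'
#' One record per header; ids are the first whitespace-delimited token of
#' each header; bases are uppercased; record order is preserved.
#'
#' @param path Path to a multi-FASTA file.
#' @return List of `sequence_record`s.
#' @export
read_fasta_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop(sprintf("no FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) stop(sprintf("empty FASTA header in %s", path))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA ids in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(ss))
  mapply(sequence_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records as multi-FASTA
#'
#' @param records List of `sequence_record`s.
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_fasta_set <- function(records, path, width = 70L) {
  ss <- Biostrings::BStringSet(
    stats::setNames(vapply(records, function(r) r$seq, character(1)),
                    vapply(records, function(r) r$id, character(1))))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# digest of the uppercased sequence (staleness detection for the cache)
.sequence_digest <- function(seq) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  writeChar(toupper(seq), con, eos = NULL)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Compute natural vectors for many records
#'
#' Per-record parallelism only (each chromosome's vector is independent),
#' so parallel and serial runs give identical results.
#'
#' @param records List of `sequence_record`s.
#' @param k Word size.
#' @param workers Number of forked workers (1 = serial).
#' @return Named list of `kmer_nv`s, in record order.
#' @export
compute_vectors <- function(records, k, workers = 1L) {
  k <- .check_k(k)
  f <- function(r) kmer_natural_vector(r, k)
  vecs <- if (workers > 1L) {
    parallel::mclapply(records, f, mc.cores = workers)
  } else {
    lapply(records, f)
  }
  stats::setNames(vecs, vapply(records, function(r) r$id, character(1)))
}

.cache_filename <- function(id, k) {
  sprintf("%s_k%d.json", gsub("[^A-Za-z0-9._-]", "_", id), k)
}

#' Cache natural vectors on disk
#'
#' Writes one JSON document per record (`{id, k, m, seq_length, n_skipped,
#' digest, entries}`; entries sorted by k-mer for reproducible diffs) plus
#' a `manifest.json` listing (id, k, digest, file).
#'
#' @param records List of `sequence_record`s.
#' @param k Word size.
#' @param cache_dir Directory (created if missing).
#' @param vectors Optional precomputed vectors (same order as records).
#' @param workers Workers for vector computation when not precomputed.
#' @return The vectors, invisibly.
#' @export
cache_vectors <- function(records, k, cache_dir, vectors = NULL,
                          workers = 1L) {
  k <- .check_k(k)
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(vectors)) vectors <- compute_vectors(records, k, workers)
  manifest <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    v <- vectors[[i]]
    dg <- .sequence_digest(r$seq)
    fn <- .cache_filename(r$id, k)
    ent <- as.data.frame(v)
    # means/moments as %.17g strings: shortest representation that
    # round-trips doubles bit-exactly through JSON
    ent$mean <- sprintf("%.17g", ent$mean)
    ent$moment <- sprintf("%.17g", ent$moment)
    doc <- list(id = r$id, k = k, m = v$m, seq_length = v$seq_length,
                n_skipped = v$n_skipped, digest = dg, entries = ent)
    jsonlite::write_json(doc, file.path(cache_dir, fn),
                         auto_unbox = TRUE, digits = NA)
    manifest[[i]] <- list(id = r$id, k = k, digest = dg, file = fn)
  }
  # merge with any manifest entries for other (id, k) combinations
  mpath <- file.path(cache_dir, "manifest.json")
  old <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = FALSE) else list()
  keys <- vapply(manifest, function(e) paste(e$id, e$k), character(1))
  old <- Filter(function(e) !(paste(e$id, e$k) %in% keys), old)
  jsonlite::write_json(c(old, manifest), mpath, auto_unbox = TRUE, digits = NA)
  invisible(vectors)
}

#' Load cached natural vectors
#'
#' Rebuilds `kmer_nv` objects from a cache directory. When `records` are
#' supplied, each record's sequence digest is checked against the cache
#' entry; mismatches (edited sequences) or missing entries are an error by
#' default, or silently dropped with `on_stale = "skip"`.
#'
#' @param cache_dir Cache directory written by [cache_vectors].
#' @param records Optional records to validate against.
#' @param k Word size to load (required when `records` given).
#' @param on_stale `"error"` or `"skip"`.
#' @return Named list of `kmer_nv`s.
#' @export
load_vectors <- function(cache_dir, records = NULL, k = NULL,
                         on_stale = c("error", "skip")) {
  on_stale <- match.arg(on_stale)
  mpath <- file.path(cache_dir, "manifest.json")
  if (!file.exists(mpath)) stop(sprintf("no cache manifest in %s", cache_dir))
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  if (!is.null(k))
    manifest <- Filter(function(e) e$k == k, manifest)
  if (!is.null(records)) {
    want <- stats::setNames(
      vapply(records, function(r) .sequence_digest(r$seq), character(1)),
      vapply(records, function(r) r$id, character(1)))
    have <- stats::setNames(vapply(manifest, function(e) e$digest, character(1)),
                            vapply(manifest, function(e) e$id, character(1)))
    stale <- names(want)[is.na(have[names(want)]) |
                           have[names(want)] != want]
    if (length(stale)) {
      if (on_stale == "error")
        stop(sprintf("stale or missing cache entries for: %s",
                     paste(stale, collapse = ", ")))
      manifest <- Filter(function(e) !(e$id %in% stale), manifest)
    }
    manifest <- Filter(function(e) e$id %in% names(want), manifest)
  }
  out <- list()
  for (e in manifest) {
    doc <- jsonlite::read_json(file.path(cache_dir, e$file),
                               simplifyVector = TRUE)
    ent <- doc$entries
    out[[doc$id]] <- .new_kmer_nv(doc$k,
                                  .kmer_to_code(ent$kmer),
                                  ent$count, as.numeric(ent$mean),
                                  as.numeric(ent$moment),
                                  doc$m, doc$seq_length,
                                  n_skipped = doc$n_skipped, id = doc$id)
  }
  out
}
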