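#' Scan promoter FASTA sequences and score every candidate site
#'
#' Runs the whole prediction pipeline on each record of a FASTA file (or a
#' record data frame): every eligible candidate cytosine (plus strand) or
#' guanine (minus strand) is windowed, encoded and scored by the ensemble,
#' and the fused score and binary call are reported. Coordinates refer to
#' the input sequence. Sequences shorter than the window produce a warning
#' and are skipped; windows containing `N` are scored but flagged.
#'
#' @param model A fitted [promethyl()] object.
#' @param fasta Path to a FASTA file, or a record data frame from
#'   [read_fasta()].
#' @param strand `"+"` or `"-"`, applied to all records (ignored when
#'   `fasta` is a data frame carrying its own strand column).
#' @return Data frame with one row per candidate: `source_id`,
#'   `center_pos` (0-based), `pos_1based`, `strand`, `window`, `score`
#'   (fused), `call` (0/1) and `has_n`.
#' @export
predict_fasta <- function(model, fasta, strand = "+") {
  stopifnot(inherits(model, "promethyl"))
  records <- if (is.data.frame(fasta)) fasta else read_fasta(fasta, strand)
  out <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    if (nchar(rec$seq) < 2L * model$delta + 1L) {
      warning("sequence '", rec$id, "' is shorter than the ",
              2L * model$delta + 1L, " nt window; skipped")
      next
    }
    cand <- scan_candidates(rec, model$delta)
    if (nrow(cand) == 0L) next
    scores <- predict_proba(model, cand)
    cand$score <- fuse_score(scores, model$score_fusion)
    cand$call <- fuse_decision(scores, model$fusion, model$threshold)
    out[[length(out) + 1L]] <- cand
  }
  if (length(out) == 0L) {
    return(data.frame(source_id = character(0), center_pos = integer(0),
                      pos_1based = integer(0), strand = character(0),
                      window = character(0), score = numeric(0),
                      call = integer(0), has_n = logical(0)))
  }
  res <- do.call(rbind, out)
  data.frame(source_id = res$source_id,
             center_pos = res$center_pos,
             pos_1based = res$center_pos + 1L,
             strand = res$source_strand,
             window = res$window,
             score = res$score,
             call = res$call,
             has_n = res$has_n,
             stringsAsFactors = FALSE)
}

#' Write candidate calls as BED6
#'
#' One BED feature per candidate site (half-open, 0-based, single-base
#' intervals); the BED score column carries the fused score scaled to
#' 0-1000.
#'
#' @param calls Data frame from [predict_fasta()].
#' @param path Output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  if (nrow(calls) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = calls$source_id,
    ranges = IRanges::IRanges(start = calls$center_pos + 1L, width = 1L),
    strand = calls$strand,
    name = sprintf("%s_5mC_%d", calls$source_id, calls$center_pos),
    score = as.integer(round(pmin(pmax(calls$score, 0), 1) * 1000)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
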