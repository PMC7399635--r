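#' Read promoter sequences from a FASTA file
#'
#' Sequences are upper-cased and validated against the DNA alphabet
#' `A, C, G, T, N`. The returned data frame has one row per record with
#' columns `id`, `seq` and `strand`; the strand defaults to `"+"` for every
#' record and can be overridden for a whole file (matching the single
#' strand choice a user makes when submitting promoter sequences).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped sequence lines).
#' @param strand `"+"` or `"-"`, applied to all records.
#' @return A data frame with columns `id`, `seq`, `strand`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1", "ACGTACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, strand = "+") {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  strand <- match.arg(strand, c("+", "-"))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records")
  }
  seqs <- toupper(as.character(set))
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("FASTA file '", path, "' has a record with an empty header")
  }
  # first whitespace-delimited token of the header is the id
  ids <- sub("\\s.*$", "", ids)
  for (i in seq_along(seqs)) {
    check_alphabet(seqs[[i]], ids[[i]])
  }
  data.frame(id = ids, seq = unname(seqs), strand = strand,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with columns `id` and `seq` (as returned by
#'   [read_fasta()] or [make_toy_promoter()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

check_alphabet <- function(seq, id = "sequence") {
  if (!nzchar(seq)) stop("record '", id, "' has an empty sequence")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("record '", id, "' contains illegal character '",
         substr(seq, bad, bad), "' at offset ", bad - 1L,
         " (0-based); allowed alphabet is A,C,G,T,N")
  }
  invisible(TRUE)
}

#' Reverse complement of a DNA string
#'
#' Complements base-wise (A<->T, C<->G, N<->N) and reverses. Applying it
#' twice returns the input.
#'
#' @param seq Character vector of DNA strings over `A,C,G,T,N`.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AAG")   # "CTT"
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- toupper(s)
    check_alphabet(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Internal constructor for the window table used throughout the package:
# one row per candidate site. `delta` is carried both as a column-free
# attribute and implied by nchar(window).
new_samples <- function(window, label = NA_integer_, source_id = NA_character_,
                        center_pos = NA_integer_, source_strand = "+") {
  delta <- (nchar(window) - 1L) %/% 2L
  out <- data.frame(window = window,
                    label = as.integer(label),
                    source_id = source_id,
                    center_pos = as.integer(center_pos),
                    source_strand = source_strand,
                    stringsAsFactors = FALSE)
  out$has_n <- grepl("N", out$window, fixed = TRUE)
  out
}

samples_delta <- function(samples) {
  L <- unique(nchar(samples$window))
  if (length(L) > 1L) {
    stop("samples mix window lengths: ", paste(L, collapse = ", "))
  }
  (L - 1L) %/% 2L
}

validate_samples <- function(samples, labeled = FALSE) {
  if (!is.data.frame(samples) || !"window" %in% names(samples)) {
    stop("samples must be a data frame with a 'window' column")
  }
  if (nrow(samples) > 0L) {
    delta <- samples_delta(samples)
    centre <- substr(samples$window, delta + 1L, delta + 1L)
    if (any(centre != "C")) {
      stop("window(s) ", paste(head(which(centre != "C"), 5L), collapse = ", "),
           " do not have C at the central position")
    }
  }
  if (labeled) {
    if (!"label" %in% names(samples) || any(is.na(samples$label))) {
      stop("samples must carry 0/1 labels")
    }
    if (!all(samples$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  }
  invisible(samples)
}

#' Extract the window around one candidate site
#'
#' Cuts the (2*delta+1)-nucleotide window centred at `center` from a
#' sequence record. On the plus strand the central base must be `C`; on the
#' minus strand it must be `G` and the window is reverse-complemented so
#' that the returned window is again C-centred. `center_pos` always refers
#' to the original, un-complemented sequence (0-based).
#'
#' @param record One-row data frame with columns `id`, `seq`, `strand`
#'   (or a list with those fields).
#' @param center 0-based position of the candidate base in `record$seq`.
#' @param delta Half-window size; the window spans `2*delta+1` bases.
#' @return One-row sample data frame (columns `window`, `label`,
#'   `source_id`, `center_pos`, `source_strand`, `has_n`).
#' @examples
#' rec <- data.frame(id = "p", seq = "AACTG", strand = "+")
#' extract_window(rec, center = 2, delta = 2)$window   # "AACTG"
#' @export
extract_window <- function(record, center, delta) {
  seq <- toupper(record$seq[[1]])
  strand <- record$strand[[1]]
  id <- record$id[[1]]
  check_alphabet(seq, id)
  L <- nchar(seq)
  if (center - delta < 0L || center + delta >= L) {
    stop("window [", center - delta, ", ", center + delta,
         "] overhangs sequence '", id, "' of length ", L)
  }
  base <- substr(seq, center + 1L, center + 1L)
  want <- if (strand == "+") "C" else "G"
  if (base != want) {
    stop("central base at position ", center, " of '", id, "' is '", base,
         "', expected '", want, "' on strand ", strand)
  }
  win <- substr(seq, center - delta + 1L, center + delta + 1L)
  if (strand == "-") win <- reverse_complement(win)
  new_samples(win, source_id = id, center_pos = center,
              source_strand = strand)
}

#' Scan a sequence for candidate 5mC sites
#'
#' Emits one unlabeled sample per eligible candidate: every `C` (plus
#' strand) or `G` (minus strand) lying at least `delta` bases from both
#' sequence ends. Windows containing `N` are kept but flagged in the
#' `has_n` column (they are excluded from training and flagged in
#' prediction reports).
#'
#' @inheritParams extract_window
#' @param record One-row data frame with columns `id`, `seq`, `strand`.
#' @return Sample data frame ordered by `center_pos`, possibly empty.
#' @examples
#' rec <- data.frame(id = "p", seq = "AACAACAA", strand = "+")
#' scan_candidates(rec, delta = 2)$center_pos   # 2 5
#' @export
scan_candidates <- function(record, delta) {
  stopifnot(delta >= 1)
  seq <- toupper(record$seq[[1]])
  check_alphabet(seq, record$id[[1]])
  strand <- record$strand[[1]]
  target <- if (strand == "+") "C" else "G"
  chars <- strsplit(seq, "")[[1]]
  pos0 <- which(chars == target) - 1L            # 0-based
  pos0 <- pos0[pos0 - delta >= 0L & pos0 + delta < length(chars)]
  if (length(pos0) == 0L) {
    return(new_samples(character(0), integer(0), character(0), integer(0),
                       character(0)))
  }
  wins <- substring(seq, pos0 - delta + 1L, pos0 + delta + 1L)
  if (strand == "-") wins <- reverse_complement(wins)
  new_samples(wins, source_id = record$id[[1]], center_pos = pos0,
              source_strand = strand)
}

#' Stratified train/test split
#'
#' Splits labeled samples into train and test sets class by class: each
#' class contributes `round(train_fraction * n)` training rows (round to
#' nearest), drawn by a seeded permutation, so the split is deterministic
#' given the seed and the per-class totals are preserved exactly.
#'
#' @param samples Labeled sample data frame (`label` column of 0/1).
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(samples, train_fraction = 0.8, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!"label" %in% names(samples) || any(is.na(samples$label))) {
    stop("split_dataset needs labeled samples")
  }
  train_idx <- integer(0)
  for (cl in sort(unique(samples$label))) {
    idx <- which(samples$label == cl)
    if (length(idx) < 2L) {
      stop("class ", cl, " has fewer than 2 members; cannot stratify")
    }
    n_train <- as.integer(round(train_fraction * length(idx)))
    perm <- with_seed(derive_seed(seed, 101L, cl), sample(idx))
    train_idx <- c(train_idx, perm[seq_len(n_train)])
  }
  train_idx <- sort(train_idx)
  list(train = samples[train_idx, , drop = FALSE],
       test = samples[setdiff(seq_len(nrow(samples)), train_idx), ,
                      drop = FALSE])
}

#' Read / write labeled window tables
#'
#' Tab-separated tables with columns `window` and `label` (plus any extra
#' columns, which are preserved) are the interchange format for training
#' data.
#'
#' @param path TSV path.
#' @return `read_samples_tsv`: a sample data frame.
#' @export
read_samples_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"window" %in% names(tab)) stop("TSV must have a 'window' column")
  tab$window <- toupper(tab$window)
  for (i in seq_len(nrow(tab))) check_alphabet(tab$window[[i]], paste0("row ", i))
  out <- new_samples(tab$window,
                     label = if ("label" %in% names(tab)) tab$label else NA,
                     source_id = if ("source_id" %in% names(tab)) tab$source_id else NA,
                     center_pos = if ("center_pos" %in% names(tab)) tab$center_pos else NA,
                     source_strand = if ("source_strand" %in% names(tab)) tab$source_strand else "+")
  validate_samples(out)
}

#' @rdname read_samples_tsv
#' @param samples Sample data frame to write.
#' @return `write_samples_tsv`: `path`, invisibly.
#' @export
write_samples_tsv <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
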