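# Label conventions: the positive class is "amyloid", the negative class is
# "non-amyloid", everywhere in the package.
LABEL_POSITIVE <- "amyloid"
LABEL_NEGATIVE <- "non-amyloid"
LABEL_LEVELS <- c(LABEL_NEGATIVE, LABEL_POSITIVE)

.label_factor <- function(x) factor(as.character(x), levels = LABEL_LEVELS)

#' Construct a labelled peptide dataset
#'
#' The unit of every pipeline in the package: an ordered collection of peptide
#' records with unique ids, uppercase sequences over the 20-letter amino-acid
#' alphabet, and a binary amyloid / non-amyloid label.
#'
#' @param id character vector of unique record ids.
#' @param sequence character vector of peptide sequences (uppercased).
#' @param label vector coercible to the two classes `"amyloid"` /
#'   `"non-amyloid"`.
#' @param source optional character vector naming the dataset of origin.
#' @return a `peptide_set`: a data frame with columns `id`, `sequence`,
#'   `label` (factor with levels non-amyloid, amyloid) and `source`.
#' @examples
#' ps <- peptide_set(c("p1", "p2"), c("NFGAIL", "DEKRHS"),
#'                   c("amyloid", "non-amyloid"))
#' class_counts(ps)
#' @export
peptide_set <- function(id, sequence, label, source = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) {
    stop("duplicate ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) stop("empty sequences are not allowed")
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), sequence)
  if (any(bad)) {
    stop("sequences with non-standard residues: ",
         paste(utils::head(id[bad], 5), collapse = ", "),
         if (sum(bad) > 5) sprintf(" (and %d more)", sum(bad) - 5L) else "")
  }
  lab <- .label_factor(label)
  if (anyNA(lab)) {
    stop("labels must be one of: ", paste(LABEL_LEVELS, collapse = ", "))
  }
  out <- data.frame(id = id, sequence = sequence, label = lab,
                    source = rep_len(as.character(source), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' Per-class record counts of a peptide set
#'
#' @param ds a `peptide_set`.
#' @return named integer vector with one count per class level
#'   (non-amyloid, amyloid).
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "peptide_set"))
  table(ds$label)
}

#' @export
print.peptide_set <- function(x, ...) {
  cc <- table(x$label)
  cat(sprintf("peptide_set: %d records (%s: %d, %s: %d)\n",
              nrow(x), LABEL_POSITIVE, cc[[LABEL_POSITIVE]],
              LABEL_NEGATIVE, cc[[LABEL_NEGATIVE]]))
  NextMethod()
}

.subset_ps <- function(ds, idx) {
  out <- ds[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peptide_set", "data.frame")
  out
}

# Drop (with a single warning giving the count) records whose sequences use
# letters outside the 20-residue alphabet (B, J, O, U, X, Z, ...): the
# property tables do not cover them.
.drop_nonstandard <- function(id, sequence) {
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
               toupper(sequence))
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-standard residues dropped",
            call. = FALSE)
  }
  list(id = id[!bad], sequence = sequence[!bad], n_dropped = sum(bad))
}

#' Read peptide records from a FASTA file
#'
#' The header token before the first whitespace becomes the record id;
#' sequences are uppercased. Records containing letters outside the standard
#' 20-residue alphabet are dropped with a warning. A sequence line appearing
#' before any header is a parse error naming the offending line.
#'
#' @param path path to a FASTA file.
#' @return data frame with columns `id` and `sequence` (no labels).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meaningful <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
  if (length(meaningful) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[meaningful[1]]), ">")) {
    stop("malformed FASTA: sequence data before any header at line ",
         meaningful[1])
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  ok <- .drop_nonstandard(ids, seqs)
  data.frame(id = unname(ok$id), sequence = unname(ok$sequence),
             stringsAsFactors = FALSE)
}

#' Write peptide records to a FASTA file
#'
#' @param records a data frame with `id` and `sequence` columns (a
#'   `peptide_set` works).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqinr::write.fasta(as.list(records$sequence), names = records$id,
                      file.out = path, as.string = TRUE, nbchar = 80)
  invisible(path)
}

# Documented label mapping: anything matching (case-insensitively) "amyloid",
# "positive", "pos", "1" maps to the positive class; "non-amyloid",
# "non_amyloid", "nonamyloid", "negative", "neg", "0" to the negative class.
.map_label <- function(x) {
  key <- tolower(trimws(as.character(x)))
  pos <- c("amyloid", "positive", "pos", "1", "amy")
  neg <- c("non-amyloid", "non_amyloid", "nonamyloid", "negative", "neg", "0",
           "non amyloid")
  out <- rep(NA_character_, length(key))
  out[key %in% pos] <- LABEL_POSITIVE
  out[key %in% neg] <- LABEL_NEGATIVE
  out
}

#' Read a labelled peptide table (TSV or CSV)
#'
#' Expects a header row with columns `id`, `sequence` and `label`. Labels are
#' mapped case-insensitively: `amyloid`/`positive`/`pos`/`1` to the positive
#' class and `non-amyloid`/`negative`/`neg`/`0` to the negative class.
#'
#' @param path path to the table.
#' @param format `"tsv"` or `"csv"`; default guessed from the file extension.
#' @return a `peptide_set`.
#' @export
read_label_table <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  need <- c("id", "sequence", "label")
  if (!all(need %in% names(tab))) {
    stop("label table must have columns id, sequence, label; found: ",
         paste(names(tab), collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate ids in label table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  lab <- .map_label(tab$label)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))
    stop("unknown label string(s) at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         ": ", paste(unique(tab$label[bad]), collapse = ", "))
  }
  seqs <- toupper(tab$sequence)
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-standard residues dropped",
            call. = FALSE)
  }
  src <- if ("source" %in% names(tab)) tab$source else NA_character_
  peptide_set(tab$id[!bad], seqs[!bad], lab[!bad],
              if (length(src) > 1) src[!bad] else src)
}

#' Write a labelled peptide table
#'
#' @param ds a `peptide_set`.
#' @param path output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(ds, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(as.data.frame(ds)[, c("id", "sequence", "label")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only sequences of a given length
#'
#' The corpus aggregation step restricts to the dominant length class
#' (hexapeptides, L = 6); relative record order is preserved.
#'
#' @param ds a `peptide_set`.
#' @param L sequence length to keep (>= 1).
#' @return the filtered `peptide_set` (possibly empty).
#' @export
filter_by_length <- function(ds, L = 6L) {
  stopifnot(inherits(ds, "peptide_set"), L >= 1)
  .subset_ps(ds, nchar(ds$sequence) == L)
}

#' Deduplicate by exact sequence
#'
#' Cross-source aggregates can contain the same peptide several times; the
#' first occurrence is kept. A duplicate carrying a conflicting label is an
#' error (the corpus would be internally inconsistent).
#'
#' @param ds a `peptide_set`.
#' @return deduplicated `peptide_set`.
#' @export
dedupe_by_sequence <- function(ds) {
  stopifnot(inherits(ds, "peptide_set"))
  first <- !duplicated(ds$sequence)
  lab_by_seq <- ds$label[first]
  names(lab_by_seq) <- ds$sequence[first]
  conflict <- ds$label != lab_by_seq[ds$sequence]
  if (any(conflict)) {
    stop("label conflict for duplicated sequence(s): ",
         paste(unique(ds$sequence[conflict]), collapse = ", "))
  }
  .subset_ps(ds, first)
}

#' Balance classes by random downsampling of the majority class
#'
#' Randomly removes majority-class records until both classes equal the
#' minority count. The removed records are returned too: the robustness
#' protocol reintroduces them into its sampling pool.
#'
#' @param ds a `peptide_set` with both classes present.
#' @param seed integer seed; the same seed always removes the same records.
#' @return list with elements `balanced` and `removed` (both `peptide_set`s).
#' @export
balance_downsample <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "peptide_set"))
  cc <- table(ds$label)
  if (any(cc == 0)) stop("both classes must be present to balance")
  minority <- min(cc)
  majority_class <- names(cc)[which.max(cc)]
  maj_idx <- which(ds$label == majority_class)
  n_remove <- length(maj_idx) - minority
  removed_idx <- withr::with_seed(seed,
    sample(maj_idx, n_remove, replace = FALSE))
  keep <- setdiff(seq_len(nrow(ds)), removed_idx)
  list(balanced = .subset_ps(ds, keep),
       removed = .subset_ps(ds, sort(removed_idx)))
}

#' Split specification for balanced train/test partitions
#'
#' @param train_per_class records per class in the training set (study
#'   default 350).
#' @param test_per_class records per class in the test set (study default 33).
#' @param seed integer seed.
#' @return a `split_spec` list.
#' @export
split_spec <- function(train_per_class = 350L, test_per_class = 33L,
                       seed = 1L) {
  stopifnot(train_per_class >= 1, test_per_class >= 1)
  structure(list(train_per_class = as.integer(train_per_class),
                 test_per_class = as.integer(test_per_class),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Draw a balanced train/test split
#'
#' Samples `train_per_class` then `test_per_class` records from each class
#' without replacement; the two partitions are disjoint by id. Leftover
#' records are reported via a message and discarded (they are not silently
#' merged into either partition).
#'
#' @param ds a `peptide_set`.
#' @param spec a [split_spec()].
#' @return list with `train` and `test` `peptide_set`s; attribute
#'   `n_discarded` records the leftover count.
#' @export
make_split <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "peptide_set"), inherits(spec, "split_spec"))
  need <- spec$train_per_class + spec$test_per_class
  cc <- table(ds$label)
  if (any(cc < need)) {
    stop(sprintf("insufficient pool: need %d per class, have %s=%d, %s=%d",
                 need, LABEL_NEGATIVE, cc[[LABEL_NEGATIVE]],
                 LABEL_POSITIVE, cc[[LABEL_POSITIVE]]))
  }
  picks <- withr::with_seed(spec$seed, {
    lapply(LABEL_LEVELS, function(cl) {
      idx <- which(ds$label == cl)
      chosen <- sample(idx, need, replace = FALSE)
      list(train = chosen[seq_len(spec$train_per_class)],
           test = chosen[spec$train_per_class + seq_len(spec$test_per_class)])
    })
  })
  train_idx <- sort(c(picks[[1]]$train, picks[[2]]$train))
  test_idx <- sort(c(picks[[1]]$test, picks[[2]]$test))
  n_discarded <- nrow(ds) - length(train_idx) - length(test_idx)
  if (n_discarded > 0) {
    message(n_discarded, " leftover record(s) discarded by the split")
  }
  out <- list(train = .subset_ps(ds, train_idx),
              test = .subset_ps(ds, test_idx))
  attr(out, "n_discarded") <- n_discarded
  out
}

#' Build distinct train/test pairs for the robustness protocol
#'
#' Repeatedly redraws balanced train (TV_i) and test (TS_i) sets from the full
#' pool (which includes the records removed at the balancing step). Pairs are
#' distinct: equality is judged by the id set of TV united with TS; a pair
#' colliding with an earlier one is redrawn, up to `retry_budget` attempts.
#'
#' @param pool a `peptide_set` (the reunified corpus).
#' @param n_pairs number of pairs (study protocol: 100).
#' @param spec a [split_spec()] giving per-class sizes (350 / 33).
#' @param seed integer seed for the whole pair sequence.
#' @param retry_budget redraw attempts per pair before erroring.
#' @return list of `n_pairs` lists, each with `index`, `train`, `test`.
#' @export
make_robustness_pairs <- function(pool, n_pairs = 100L, spec = split_spec(),
                                  seed = 1L, retry_budget = 1000L) {
  stopifnot(inherits(pool, "peptide_set"), n_pairs >= 1)
  need <- spec$train_per_class + spec$test_per_class
  cc <- table(pool$label)
  if (any(cc < need)) {
    stop(sprintf("pool too small for one split: need %d per class", need))
  }
  withr::with_seed(seed, {
    seen <- character(0)
    pairs <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      ok <- FALSE
      for (attempt in seq_len(retry_budget)) {
        idx_by_class <- lapply(LABEL_LEVELS, function(cl) {
          sample(which(pool$label == cl), need, replace = FALSE)
        })
        train_idx <- sort(unlist(lapply(idx_by_class, function(v)
          v[seq_len(spec$train_per_class)])))
        test_idx <- sort(unlist(lapply(idx_by_class, function(v)
          v[spec$train_per_class + seq_len(spec$test_per_class)])))
        key <- paste(sort(pool$id[c(train_idx, test_idx)]), collapse = "\r")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          pairs[[i]] <- list(index = i,
                             train = .subset_ps(pool, train_idx),
                             test = .subset_ps(pool, test_idx))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not generate ", n_pairs, " distinct pairs within ",
             retry_budget, " attempts per pair (stuck at pair ", i, ")")
      }
    }
    pairs
  })
}

#' Write a split manifest
#'
#' Records every id/sequence/label with its partition so a run is exactly
#' reconstructable.
#'
#' @param split a list with `train` and `test` `peptide_set`s.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  rows <- rbind(
    cbind(as.data.frame(split$train)[, c("id", "sequence", "label")],
          partition = "train"),
    cbind(as.data.frame(split$test)[, c("id", "sequence", "label")],
          partition = "test"))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
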