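#' Parse an IEDB-style affinity table
#'
#' Reads a tab-separated table of binding measurements with columns for the
#' allele name, the peptide sequence, the measurement type (`ic50`, `binary`
#' or `t1/2`) and the measurement value (nM for `ic50`, minutes for `t1/2`,
#' 0/1 for `binary`). Rows are validated against the allele index and the
#' encoder's alphabet; surviving rows get derived training labels
#' (`log_ic50`, `binary_label`).
#'
#' Rows are dropped — and counted in the parse report attached as the
#' `"parse_report"` attribute — when the peptide is not a valid 9-mer
#' (`dropped_length`), the allele is absent from `alleles`
#' (`dropped_allele`), the value cannot be parsed (`dropped_value`), or the
#' row duplicates an earlier (allele, peptide, type) triple
#' (`dropped_duplicate`; the first occurrence is kept). Inequality-qualified
#' values such as `">20000"` are read as their numeric bound.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param alleles Named character vector mapping allele name to aligned
#'   sequence (see [read_allele_fasta()]).
#' @param col_map Optional named character vector translating the canonical
#'   column names `allele`, `peptide`, `measurement_type`,
#'   `measurement_value` to the names used in the file (for other table
#'   dialects, e.g. IEDB weekly benchmark exports).
#' @return A tibble of binding samples with columns `allele`, `peptide`,
#'   `measurement_type`, `measurement_value`, `log_ic50`, `binary_label`,
#'   carrying the parse report as an attribute (see [parse_report()]).
#' @export
read_affinity_table <- function(path, alleles, col_map = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  canonical <- c("allele", "peptide", "measurement_type", "measurement_value")
  if (!is.null(col_map)) {
    missing_map <- setdiff(canonical, names(col_map))
    if (length(missing_map)) {
      abort(paste("col_map must name:", paste(missing_map, collapse = ", ")),
            class = "panbinder_format_error")
    }
    if (!all(col_map %in% names(raw))) {
      abort("col_map refers to columns absent from the file",
            class = "panbinder_format_error")
    }
    raw <- dplyr::rename(raw, !!!setNames(col_map, canonical))
  }
  missing_cols <- setdiff(canonical, names(raw))
  if (length(missing_cols)) {
    abort(paste("affinity table is missing required columns:",
                paste(missing_cols, collapse = ", ")),
          class = "panbinder_format_error")
  }
  as_binding_samples(raw, alleles)
}

#' Validate a data frame of binding measurements
#'
#' The in-memory counterpart of [read_affinity_table()]: validates rows,
#' deduplicates on (allele, peptide, measurement type) keeping the first
#' occurrence, and derives the training labels. Used both by the file reader
#' and by the synthetic generator.
#'
#' @param x Data frame with columns `allele`, `peptide`, `measurement_type`,
#'   `measurement_value` (values may be character, possibly qualified with
#'   `<`/`>`).
#' @inheritParams read_affinity_table
#' @return A tibble of binding samples (see [read_affinity_table()]).
#' @export
as_binding_samples <- function(x, alleles) {
  stopifnot(is.data.frame(x))
  x <- as_tibble(x)
  x$peptide <- toupper(as.character(x$peptide))
  x$allele <- as.character(x$allele)
  type <- tolower(as.character(x$measurement_type))
  type[type %in% c("t1/2", "t half", "thalf")] <- "t_half"
  x$measurement_type <- type

  value_chr <- as.character(x$measurement_value)
  value <- suppressWarnings(as.numeric(sub("^\\s*[<>]=?\\s*", "", value_chr)))

  ok_pep <- nchar(x$peptide) == 9L &
    !grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), x$peptide)
  ok_allele <- x$allele %in% names(alleles)
  ok_type <- x$measurement_type %in% c("ic50", "binary", "t_half")
  ok_value <- !is.na(value) & value >= 0 &
    !(x$measurement_type == "binary" & !value %in% c(0, 1))

  report <- list(
    n_rows = nrow(x),
    dropped_length = sum(!ok_pep),
    dropped_allele = sum(ok_pep & !ok_allele),
    dropped_value = sum(ok_pep & ok_allele & !(ok_value & ok_type))
  )
  keep <- ok_pep & ok_allele & ok_value & ok_type
  x <- x[keep, , drop = FALSE]
  value <- value[keep]

  dup <- duplicated(x[, c("allele", "peptide", "measurement_type")])
  report$dropped_duplicate <- sum(dup)
  x <- x[!dup, , drop = FALSE]
  value <- value[!dup]

  if (nrow(x) == 0L) {
    abort("no valid binding samples after parsing", class = "panbinder_empty_dataset")
  }

  is_ic50 <- x$measurement_type == "ic50"
  is_bin <- x$measurement_type == "binary"
  is_t <- x$measurement_type == "t_half"
  value[is_ic50] <- pmin(value[is_ic50], 80000)

  out <- tibble(
    allele = x$allele,
    peptide = x$peptide,
    measurement_type = x$measurement_type,
    measurement_value = value,
    log_ic50 = ifelse(is_ic50, log_ic50(pmax(value, 0)), NA_real_),
    binary_label = NA_integer_
  )
  out$binary_label[is_ic50] <- binarize_ic50(value[is_ic50])
  out$binary_label[is_bin] <- as.integer(value[is_bin])
  out$binary_label[is_t] <- binarize_t_half(value[is_t])
  attr(out, "parse_report") <- report
  out
}

#' Retrieve the parse report of an affinity table
#'
#' @param samples A tibble returned by [read_affinity_table()] or
#'   [as_binding_samples()].
#' @return A list with counts `n_rows`, `dropped_length`, `dropped_allele`,
#'   `dropped_value`, `dropped_duplicate`.
#' @export
parse_report <- function(samples) {
  attr(samples, "parse_report")
}

#' Write binding samples as a tab-separated affinity table
#'
#' @param samples Tibble of binding samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(samples, path) {
  readr::write_tsv(samples[, c("allele", "peptide", "measurement_type",
                               "measurement_value")], path, progress = FALSE)
  invisible(path)
}

#' Greedy peptide redundancy filter
#'
#' Removes near-duplicate peptides by greedy single-linkage-to-representative
#' clustering at a sequence identity threshold, the scheme CD-HIT popularised.
#' Unique peptides are ordered by descending sample count (ties broken
#' lexicographically); each peptide joins the first existing cluster whose
#' representative shares at least `ceiling(9 * identity_threshold)` identical
#' positions with it, and founds a new cluster otherwise. Only the samples of
#' cluster representatives (the peptide with the greatest number of samples
#' in its cluster, by construction the founder) are kept. Identity between
#' two 9-mers is ungapped positional identity, matches / 9.
#'
#' The operation is idempotent: surviving representatives are pairwise below
#' the identity threshold.
#'
#' @param samples Tibble of binding samples; all peptides must be 9-mers.
#' @param identity_threshold Fraction in (0, 1]; default 0.7.
#' @return The filtered tibble of samples.
#' @export
filter_redundant <- function(samples, identity_threshold = 0.7) {
  stopifnot(is.data.frame(samples))
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1L ||
      identity_threshold <= 0 || identity_threshold > 1) {
    abort("identity_threshold must lie in (0, 1]", class = "panbinder_domain_error")
  }
  counts <- samples |>
    dplyr::count(.data$peptide, name = "n_samples") |>
    dplyr::arrange(dplyr::desc(.data$n_samples), .data$peptide)
  peps <- counts$peptide
  if (any(nchar(peps) != 9L)) {
    abort("redundancy filter requires 9-mer peptides", class = "panbinder_length_error")
  }
  min_matches <- ceiling(9 * identity_threshold)

  pm <- matrix(unlist(strsplit(peps, "", fixed = TRUE), use.names = FALSE),
               ncol = 9L, byrow = TRUE)
  reps <- integer(0)            # row indices of cluster representatives
  rep_mat <- NULL               # their residue matrix, rows in founding order
  for (i in seq_along(peps)) {
    joined <- FALSE
    if (length(reps)) {
      matches <- rowSums(rep_mat == matrix(pm[i, ], nrow = length(reps),
                                           ncol = 9L, byrow = TRUE))
      joined <- any(matches >= min_matches)
    }
    if (!joined) {
      reps <- c(reps, i)
      rep_mat <- rbind(rep_mat, pm[i, , drop = FALSE])
    }
  }
  samples[samples$peptide %in% peps[reps], , drop = FALSE]
}

#' Random train/validation split
#'
#' Randomly splits binding samples into a training and a validation set at a
#' 4:1 ratio (training size `ceiling(prop * n)`), deterministically for a
#' given seed.
#'
#' @param samples Tibble of binding samples, at least 5 rows.
#' @param seed Integer seed.
#' @param prop Training proportion, default 0.8.
#' @return A list with tibbles `train` and `val`; disjoint, union the input.
#' @export
split_train_val <- function(samples, seed, prop = 0.8) {
  stopifnot(is.data.frame(samples))
  n <- nrow(samples)
  if (n < 5L) {
    abort("need at least 5 samples to split 4:1", class = "panbinder_size_error")
  }
  n_train <- ceiling(prop * n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = samples[sort(idx), , drop = FALSE],
       val = samples[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Leave-one-allele-out folds
#'
#' Builds one fold per allele: the held-out allele's samples form the test
#' set and every other allele's samples the training set, mimicking
#' prediction on an allele never seen in training.
#'
#' @param samples Tibble of binding samples covering at least 2 alleles.
#' @return A tibble with columns `allele`, `train` (list of tibbles), `test`
#'   (list of tibbles); each fold's train and test partition the input.
#' @export
loao_folds <- function(samples) {
  stopifnot(is.data.frame(samples))
  alleles <- sort(unique(samples$allele))
  if (length(alleles) < 2L) {
    abort("leave-one-allele-out needs at least 2 alleles",
          class = "panbinder_fold_error")
  }
  tibble(
    allele = alleles,
    train = lapply(alleles, function(a) samples[samples$allele != a, , drop = FALSE]),
    test = lapply(alleles, function(a) samples[samples$allele == a, , drop = FALSE])
  )
}
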