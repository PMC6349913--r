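#' A planted cross-allele binding rule
#'
#' Defines the ground truth used by the synthetic data generator. Nine fixed
#' *contact positions* within the 372-column HLA alignment — the same
#' positions for every allele, mirroring how the true peptide-contacting
#' pocket positions are extremely conserved across class I molecules — pair
#' peptide position `j` with alignment column `contact_positions[j]`. A
#' 20 x 20 compatibility table assigns each (peptide residue, HLA contact
#' residue) pair an energy contribution; the binding energy of a pair is the
#' sum over the nine contacts and maps to a log IC50 via
#' `mu + gamma * E + Normal(0, sigma)`.
#'
#' Alongside the contact positions the model fixes a *pocket repertoire*:
#' for each contact position, a small set of residues
#' (`repertoire_size`, default 4) from which alleles draw their contact
#' residue. This mirrors how real class I binding pockets vary over a
#' restricted, conserved set of residues (the basis of HLA supertypes)
#' rather than freely — and it is what makes generalization to an unseen
#' allele possible at small allele counts: a held-out allele's pocket
#' residues have almost surely been observed, at the same positions, in
#' other alleles.
#'
#' Defaults: `mu = log(500)` centers the population on the 500 nM class
#' boundary so both classes occur; `gamma = 1`; `sigma = 0.5` adds label
#' noise on the scale of inter-assay variability; compatibility entries are
#' standard normal draws.
#'
#' @param seed Integer seed fixing the contact positions, the table and the
#'   pocket repertoire.
#' @param contact_positions Optional integer vector of 9 distinct alignment
#'   columns in 1..372; drawn at random when `NULL`.
#' @param gamma,mu,sigma Affine map and noise parameters from energy to log
#'   IC50.
#' @param repertoire_size Number of candidate residues per contact position
#'   (2..20).
#' @return An object of class `planted_binding_model`.
#' @export
planted_binding_model <- function(seed = 42L, contact_positions = NULL,
                                  gamma = 1, mu = log(500), sigma = 0.5,
                                  repertoire_size = 4L) {
  if (!is.numeric(repertoire_size) || repertoire_size < 2L || repertoire_size > 20L) {
    abort("repertoire_size must lie in 2..20", class = "panbinder_domain_error")
  }
  model <- withr::with_seed(seed, {
    cp <- contact_positions %||% sort(sample.int(HLA_WIDTH, 9L))
    compat <- matrix(rnorm(400), 20L, 20L,
                     dimnames = list(aa_alphabet(), aa_alphabet()))
    repertoire <- t(vapply(1:9, function(j) sort(sample.int(20L, repertoire_size)),
                           integer(repertoire_size)))
    list(contact_positions = as.integer(cp), compat = compat,
         pocket_repertoire = repertoire,
         gamma = gamma, mu = mu, sigma = sigma, seed = as.integer(seed))
  })
  if (length(model$contact_positions) != 9L ||
      anyDuplicated(model$contact_positions) ||
      any(model$contact_positions < 1L | model$contact_positions > HLA_WIDTH)) {
    abort("contact_positions must be 9 distinct alignment columns in 1..372",
          class = "panbinder_domain_error")
  }
  structure(model, class = "planted_binding_model")
}

#' Generate synthetic aligned HLA alleles
#'
#' Builds a width-372 consensus sequence and derives each allele from it by
#' substituting residues at, and with probability 1/2 around, the model's
#' contact positions (polymorphism concentrated where it matters for
#' binding), plus a low background substitution rate elsewhere. Contact
#' residues are drawn from the model's per-position pocket repertoire (see
#' [planted_binding_model()]); flank and background substitutions are
#' unrestricted. Allele names cycle through the HLA-A/-B/-C loci so
#' per-locus reporting is exercised.
#'
#' @param model A [planted_binding_model()].
#' @param n_alleles Number of alleles (>= 1).
#' @param seed Integer seed.
#' @param background_rate Per-column substitution probability away from the
#'   contact region.
#' @return Named character vector of aligned sequences (an allele index).
#' @export
generate_alleles <- function(model, n_alleles, seed = 1L, background_rate = 0.01) {
  stopifnot(inherits(model, "planted_binding_model"))
  if (!is.numeric(n_alleles) || n_alleles < 1L) {
    abort("n_alleles must be at least 1", class = "panbinder_domain_error")
  }
  n_alleles <- as.integer(n_alleles)
  aa <- aa_alphabet()
  withr::with_seed(seed, {
    consensus <- sample(aa, HLA_WIDTH, replace = TRUE)
    near <- unique(pmin(pmax(
      rep(model$contact_positions, each = 3L) + (-1L):1L, 1L), HLA_WIDTH))
    rep_size <- ncol(model$pocket_repertoire)
    seqs <- character(n_alleles)
    for (i in seq_len(n_alleles)) {
      s <- consensus
      s[model$contact_positions] <-
        aa[model$pocket_repertoire[cbind(1:9, sample.int(rep_size, 9L, replace = TRUE))]]
      flank <- setdiff(near, model$contact_positions)
      hit <- flank[runif(length(flank)) < 0.5]
      s[hit] <- sample(aa, length(hit), replace = TRUE)
      bg <- setdiff(which(runif(HLA_WIDTH) < background_rate), near)
      s[bg] <- sample(aa, length(bg), replace = TRUE)
      seqs[i] <- paste(s, collapse = "")
    }
    locus <- c("A", "B", "C")[(seq_len(n_alleles) - 1L) %% 3L + 1L]
    names(seqs) <- sprintf("HLA-%s*90:%02d", locus, seq_len(n_alleles))
    seqs
  })
}

#' Ground-truth binding energy of a peptide–allele pair
#'
#' `E = sum_j compat[peptide[j], allele[contact_positions[j]]]` over the nine
#' contacts; a gap at a contact position contributes the neutral energy 0.
#' Lower energy means stronger binding (lower IC50) under the generator's
#' default `gamma > 0`.
#'
#' @param peptide A 9-mer string.
#' @param allele_seq Aligned HLA sequence (residues and `-`).
#' @param model A [planted_binding_model()].
#' @return A single numeric energy.
#' @export
true_energy <- function(peptide, allele_seq, model) {
  stopifnot(inherits(model, "planted_binding_model"))
  pep <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  if (length(pep) != 9L) {
    abort("peptide must be a 9-mer", class = "panbinder_length_error")
  }
  hla <- strsplit(toupper(allele_seq), "", fixed = TRUE)[[1]]
  contact <- hla[model$contact_positions]
  pi <- aa_channel(pep)
  hi <- aa_channel(contact)
  if (anyNA(pi)) abort("invalid peptide residue", class = "panbinder_alphabet_error")
  ok <- !is.na(hi)  # gap (or out-of-range column) is energy-neutral
  sum(model$compat[cbind(pi[ok], hi[ok])])
}

# energies for many peptides against one allele, vectorized
true_energy_many <- function(peptides, allele_seq, model) {
  hla <- strsplit(toupper(allele_seq), "", fixed = TRUE)[[1]]
  hi <- aa_channel(hla[model$contact_positions])
  pm <- matrix(aa_channel(matrix(unlist(strsplit(toupper(peptides), "", fixed = TRUE),
                                        use.names = FALSE), ncol = 9L, byrow = TRUE)),
               ncol = 9L)
  e <- numeric(length(peptides))
  for (j in which(!is.na(hi))) {
    e <- e + model$compat[cbind(pm[, j], hi[j])]
  }
  e
}

#' Generate a synthetic pan-specific binding dataset
#'
#' Draws `n_per_allele` 9-mer peptides per allele: a `1 - binder_fraction`
#' share sampled uniformly over residues and a binder quota sampled
#' per-position from a Boltzmann distribution over the allele's contact
#' energies (`P(residue) ~ exp(-compat/temperature)`), which plants strong
#' binders for every allele and keeps the two label classes populated. Each
#' pair's log IC50 is `mu + gamma * E + Normal(0, sigma)` clamped to
#' `[0, log(80000)]`, and the IC50 label written to the affinity table is
#' its exponential, so every IC50 lies in the measurable \[0, 80000\] nM
#' range.
#'
#' @param alleles Allele index from [generate_alleles()].
#' @param n_per_allele Samples per allele (>= 1).
#' @param model The [planted_binding_model()] the alleles were built for.
#' @param seed Integer seed.
#' @param binder_fraction Share of planted low-energy binders per allele.
#' @param temperature Boltzmann temperature of the binder sampler.
#' @return A list of class `synthetic_dataset`: `samples` (parsed binding
#'   samples, measurement type `ic50`), `alleles`, `truth` (sidecar tibble
#'   with the ground-truth energy and noise-free log IC50 per row) and
#'   `model`.
#' @export
generate_samples <- function(alleles, n_per_allele, model, seed = 1L,
                             binder_fraction = 0.3, temperature = 0.5) {
  stopifnot(inherits(model, "planted_binding_model"))
  if (!is.numeric(n_per_allele) || n_per_allele < 1L) {
    abort("n_per_allele must be at least 1", class = "panbinder_domain_error")
  }
  n_per_allele <- as.integer(n_per_allele)
  aa <- aa_alphabet()
  rows <- withr::with_seed(seed, {
    purrr::map(names(alleles), function(al) {
      n_bind <- round(binder_fraction * n_per_allele)
      n_unif <- n_per_allele - n_bind
      pep_unif <- apply(matrix(sample(aa, 9L * n_unif, replace = TRUE),
                               n_unif, 9L), 1L, paste, collapse = "")
      hla <- strsplit(toupper(alleles[[al]]), "", fixed = TRUE)[[1]]
      hi <- aa_channel(hla[model$contact_positions])
      pep_bind <- if (n_bind > 0L) {
        cols <- lapply(seq_len(9L), function(j) {
          w <- if (is.na(hi[j])) rep(1, 20L) else exp(-model$compat[, hi[j]] / temperature)
          sample(aa, n_bind, replace = TRUE, prob = w)
        })
        do.call(paste0, cols)
      } else character(0)
      peps <- c(pep_unif, pep_bind)
      e <- true_energy_many(peps, alleles[[al]], model)
      log_true <- model$mu + model$gamma * e
      log_obs <- pmin(pmax(log_true + rnorm(length(e), sd = model$sigma), 0),
                      log(80000))
      tibble(allele = al, peptide = peps, measurement_type = "ic50",
             measurement_value = exp(log_obs), energy = e,
             log_ic50_true = log_true)
    }) |> dplyr::bind_rows()
  })
  samples <- as_binding_samples(
    rows[, c("allele", "peptide", "measurement_type", "measurement_value")],
    alleles)
  truth <- dplyr::semi_join(rows, samples,
                            by = c("allele", "peptide", "measurement_type"))
  truth <- truth[!duplicated(truth[, c("allele", "peptide")]), , drop = FALSE]
  structure(list(samples = samples, alleles = alleles,
                 truth = truth[, c("allele", "peptide", "energy", "log_ic50_true")],
                 model = model),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset in the pipeline's file formats
#'
#' Emits the tab-separated affinity table, the aligned-allele FASTA and a
#' ground-truth sidecar table (peptide, allele, energy, noise-free log
#' IC50), i.e. exactly the inputs the real pipeline consumes plus the
#' generator's truth.
#'
#' @param dataset A `synthetic_dataset` from [generate_samples()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(affinity = file.path(dir, "affinity.tsv"),
             alleles = file.path(dir, "alleles.fasta"),
             truth = file.path(dir, "truth.tsv"))
  write_affinity_table(dataset$samples, paths[["affinity"]])
  write_allele_fasta(dataset$alleles, paths[["alleles"]])
  readr::write_tsv(dataset$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
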