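test_that("AUC matches brute-force pair counting", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1)
  expect_equal(auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)

  withr::with_seed(44, {
    for (i in 1:100) {
      n <- sample(4:50, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- sample(round(rnorm(n), 1))  # rounded to force ties
      expect_equal(auc(scores, labels), auc_bruteforce(scores, labels))
    }
  })
  expect_error(auc(1:3, c(1, 1, 1)), class = "panbinder_undefined_metric")
})

test_that("SRCC matches the d^2 formula on tie-free data and handles edge cases", {
  expect_equal(srcc(1:4, c(1, 3, 2, 4)), 0.8)
  x <- c(3, 1, 4, 2, 5)
  expect_equal(srcc(x, x), 1)
  expect_equal(srcc(x, -x), -1)
  withr::with_seed(45, {
    for (i in 1:100) {
      n <- sample(3:40, 1)
      x <- sample(n)  # tie-free ranks
      y <- rnorm(n)
      expect_equal(srcc(x, y), srcc_d2(x, y))
    }
  })
  expect_error(srcc(rep(2, 5), 1:5), class = "panbinder_undefined_metric")
  expect_error(srcc(1:3, 1:4), class = "panbinder_shape_error")
})

test_that("score orientation: lower predicted IC50 outranks, AUC is rank-invariant", {
  pred <- tibble::tibble(log_ic50_pred = log(c(10, 5000)),
                         binding_prob = c(0.9, 0.1))
  sc <- score_direction(pred)
  expect_gt(sc$affinity_score[1], sc$affinity_score[2])
  expect_identical(sc$prob_score, pred$binding_prob)

  withr::with_seed(46, {
    log_pred <- rnorm(40, 6, 2)
    labels <- c(0, 1, sample(0:1, 38, replace = TRUE))
    a1 <- auc(-log_pred, labels)
    a2 <- auc(-exp(log_pred), labels)  # -IC50: monotone transform of -logIC50
    expect_equal(a1, a2)
    expect_equal(auc(log_pred, labels), 1 - a1)  # sign flip mirrors AUC
  })
})

test_that("consistency report applies the dual 500 nM / 0.5 rule", {
  pred <- tibble::tibble(
    ic50_pred = c(100, 100, 600),
    log_ic50_pred = log(c(100, 100, 600)),
    binding_prob = c(0.9, 0.2, 0.2),
    binary_label = c(1L, 1L, 0L)
  )
  r <- consistency_report(pred)
  expect_equal(r$consistent_frac, 2 / 3)
  expect_equal(r$correct_ic50_frac, 1)     # 100<=500 binding x2, 600>500 not
  expect_equal(r$correct_binary_frac, 2 / 3)

  allbind <- tibble::tibble(ic50_pred = 1, log_ic50_pred = 0, binding_prob = 1,
                            binary_label = rep(1L, 4))
  expect_equal(consistency_report(allbind)$consistent_frac, 1)

  # a probability head that is a decreasing function of predicted logIC50
  # always yields a negative correlation between the two outputs
  lp <- withr::with_seed(47, rnorm(200, 6, 2))
  sig <- tibble::tibble(ic50_pred = exp(lp), log_ic50_pred = lp,
                        binding_prob = 1 / (1 + exp(lp - log(500))),
                        binary_label = rep(c(0L, 1L), 100))
  expect_lt(consistency_report(sig)$pearson_r, 0)
  expect_lt(consistency_report(sig)$slope, 0)

  # invariant to row order
  perm <- withr::with_seed(48, sample(nrow(sig)))
  expect_equal(consistency_report(sig[perm, ]), consistency_report(sig))

  expect_error(consistency_report(sig[0, ]), class = "panbinder_size_error")
})

test_that("evaluation report covers all / locus / allele groups", {
  al <- toy_alleles()
  net <- build_network(network_config("compact", seed = 5))
  samples <- toy_samples(al, n_per_allele = 25)
  pred <- predict(net, samples, al)
  rep <- evaluate_predictions(pred)
  expect_setequal(unique(rep$group_type), c("all", "locus", "allele"))
  expect_equal(sum(rep$group_type == "allele"), 3)
  expect_true(all(rep$n >= 1))
  ok <- !is.na(rep$auc_prob)
  expect_true(all(rep$auc_prob[ok] >= 0 & rep$auc_prob[ok] <= 1))
  # loci come from the allele-name prefix
  expect_setequal(rep$group[rep$group_type == "locus"],
                  unique(sub("^(HLA-[A-Z]).*", "\\1", samples$allele)))
})

test_that("cross-validation folds partition the data and pool predictions", {
  al <- toy_alleles()
  samples <- toy_samples(al, n_per_allele = 25)
  cv <- run_cv(samples, al, k = 3, seed = 7,
               config = network_config("compact"), epochs = 0)
  expect_equal(nrow(cv$predictions), nrow(samples))
  key <- paste(cv$predictions$allele, cv$predictions$peptide)
  expect_setequal(key, paste(samples$allele, samples$peptide))
  expect_false(any(duplicated(key)))
  expect_equal(sort(unique(cv$predictions$fold)), 1:3)
  expect_error(run_cv(samples, al, k = 1), class = "panbinder_size_error")
})

test_that("an untrained model scores at chance on balanced data", {
  m <- planted_binding_model(seed = 201)
  al <- generate_alleles(m, 5, seed = 202)
  ds <- generate_samples(al, 400, m, seed = 203)
  cv <- run_cv(ds$samples, al, k = 2, seed = 204,
               config = network_config("compact"), epochs = 0)
  pooled <- cv$report[cv$report$group_type == "all", ]
  expect_lt(abs(pooled$auc_prob - 0.5), 0.05)
  expect_lt(abs(pooled$auc_affinity - 0.5), 0.05)
})

test_that("LOAO harness never trains on the held-out allele", {
  al <- toy_alleles()
  samples <- toy_samples(al, n_per_allele = 25)
  lo <- run_loao(samples, al, seed = 7,
                 config = network_config("compact"), epochs = 0)
  expect_equal(nrow(lo$per_allele), 3)
  expect_setequal(lo$per_allele$allele, names(al))
  expect_equal(nrow(lo$predictions), nrow(samples))
  split_by <- split(lo$predictions$allele, lo$predictions$held_out)
  for (held in names(split_by)) {
    expect_identical(unique(split_by[[held]]), held)
  }
})

test_that("benchmark scoring respects measurement types and stays robust", {
  al <- toy_alleles()
  net <- build_network(network_config("compact", seed = 5))
  bench <- tibble::tibble(
    allele = names(al)[c(1, 1, 1, 1, 2, 2, 2, 3, 3)],
    peptide = c(random_peptides(4, seed = 61), random_peptides(3, seed = 62),
                random_peptides(2, seed = 63)),
    measurement_type = c(rep("binary", 4), rep("t1/2", 3), rep("ic50", 2)),
    measurement_value = c("1", "0", "1", "0", "30", "500", "80", "10", "20")
  ) |> as_binding_samples(al)
  rep <- evaluate_benchmark(net, bench, al)
  bin_row <- rep[rep$measurement_type == "binary", ]
  expect_true(is.na(bin_row$srcc_affinity))   # no SRCC for binary datasets
  expect_false(is.na(bin_row$auc_prob))
  t_row <- rep[rep$measurement_type == "t_half", ]
  expect_false(is.na(t_row$srcc_affinity))    # SRCC on negated minutes
  ic_row <- rep[rep$measurement_type == "ic50", ]
  expect_true(is.na(ic_row$auc_prob))         # single-class: undefined, not an error

  # duplicate peptides within a dataset are dropped before scoring
  dup <- bench[c(1, 1, 2, 3, 4), ]
  rep2 <- evaluate_benchmark(net, dup, al)
  expect_equal(rep2$n, 4)

  # no overlap with the allele index is a coverage error
  other <- bench
  other$allele <- "HLA-A*00:00"
  expect_error(evaluate_benchmark(net, other, al),
               class = "panbinder_coverage_error")
})
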