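#' Network architecture configuration
#'
#' Describes the dual-encoder architecture: a peptide encoder (two blocks of
#' convolution + batch normalization + leaky ReLU mapping 1x9x20 to 1x9x10),
#' a VGG-style HLA encoder (convolution blocks with width-halving max pools,
#' an adaptive width-9 average pool and a 1x1 convolution, mapping 1x372x21
#' to 1x9x10), a binding-context extractor of two locally connected blocks
#' (valid padding, no weight sharing across positions) that flattens to the
#' 2560-dimensional binding context vector, and two predictor heads (one
#' hidden dense layer each) for log IC50 regression and binding probability
#' classification.
#'
#' Two presets are provided: `"default"` (encoder filters 32/10 and
#' 32-64-128, extractor filters 128/512) and `"compact"`, a reduced variant
#' with fewer encoder/extractor filters for fast CPU experiments. Both
#' satisfy the architectural contract: encoder outputs 1x9x10, concatenated
#' feature tensor 1x9x20, context vector length exactly 2560 (with kernel
#' width 3 the extractor widths are 9 -> 7 -> 5, so the final filter count
#' must be 512).
#'
#' @param preset `"default"` or `"compact"`.
#' @param peptide_filters Integer vector of the two peptide-encoder filter
#'   counts; the second must be 10.
#' @param hla_filters Integer vector of the three HLA-encoder filter counts.
#' @param extractor_filters Integer vector of the two locally connected
#'   filter counts; with kernel width 3 the second must be 512 so the
#'   flattened context has length 2560.
#' @param head_hidden_units Hidden units in each predictor head.
#' @param kernel_width Convolution / locally-connected kernel width.
#' @param leaky_slope Negative slope of the leaky ReLU activations.
#' @param seed Integer seed for deterministic weight initialization.
#' @return An object of class `panbinder_config`.
#' @export
network_config <- function(preset = c("default", "compact"),
                           peptide_filters = NULL,
                           hla_filters = NULL,
                           extractor_filters = NULL,
                           head_hidden_units = 64L,
                           kernel_width = 3L,
                           leaky_slope = 0.3,
                           seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    default = list(pep = c(32L, 10L), hla = c(32L, 64L, 128L), ext = c(128L, 512L)),
    compact = list(pep = c(16L, 10L), hla = c(16L, 32L, 32L), ext = c(64L, 512L))
  )
  cfg <- structure(list(
    preset = preset,
    peptide_filters = as.integer(peptide_filters %||% defaults$pep),
    hla_filters = as.integer(hla_filters %||% defaults$hla),
    extractor_filters = as.integer(extractor_filters %||% defaults$ext),
    head_hidden_units = as.integer(head_hidden_units),
    kernel_width = as.integer(kernel_width),
    leaky_slope = leaky_slope,
    seed = as.integer(seed)
  ), class = "panbinder_config")
  validate_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(cfg) {
  k <- cfg$kernel_width
  if (length(cfg$peptide_filters) != 2L || cfg$peptide_filters[2] != 10L) {
    abort("peptide encoder must end in 10 filters (output 1 x 9 x 10)",
          class = "panbinder_construction_error")
  }
  if (length(cfg$hla_filters) != 3L) {
    abort("HLA encoder expects 3 convolution stages",
          class = "panbinder_construction_error")
  }
  if (length(cfg$extractor_filters) != 2L) {
    abort("extractor expects 2 locally connected blocks",
          class = "panbinder_construction_error")
  }
  w1 <- 9L - k + 1L
  w2 <- w1 - k + 1L
  if (w2 < 1L || w2 * cfg$extractor_filters[2] != 2560L) {
    abort(sprintf(
      "extractor flatten length %d != 2560; with kernel width %d the final block needs %s filters",
      max(w2, 0L) * cfg$extractor_filters[2], k,
      if (w2 >= 1L) as.character(2560L %/% w2) else "a narrower kernel"),
      class = "panbinder_construction_error")
  }
  invisible(cfg)
}

#' Build a network with deterministic initial weights
#'
#' Instantiates all trainable parameters of the architecture described by a
#' [network_config()]: He-normal weights for convolutional, locally
#' connected and dense layers, unit scale / zero shift for batch
#' normalization. Initialization is a pure function of `config$seed`, so the
#' same config always yields bit-identical parameters.
#'
#' @param config A [network_config()] object.
#' @return An object of class `panbinder_network` holding the parameter
#'   stacks of both encoders, the extractor and the two heads.
#' @export
build_network <- function(config) {
  validate_config(config)
  k <- config$kernel_width
  s <- config$leaky_slope
  pf <- config$peptide_filters
  hf <- config$hla_filters
  ef <- config$extractor_filters
  hh <- config$head_hidden_units
  w1 <- 9L - k + 1L
  w2 <- w1 - k + 1L
  net <- withr::with_seed(config$seed, {
    list(
      pep = list(
        layer_conv(k, 20L, pf[1], bias = FALSE), layer_bn(pf[1]), layer_lrelu(s),
        layer_conv(k, pf[1], pf[2], bias = FALSE), layer_bn(pf[2]), layer_lrelu(s)
      ),
      hla = list(
        layer_conv(k, 21L, hf[1], bias = FALSE), layer_bn(hf[1]), layer_lrelu(s), layer_maxpool(),
        layer_conv(k, hf[1], hf[2], bias = FALSE), layer_bn(hf[2]), layer_lrelu(s), layer_maxpool(),
        layer_conv(k, hf[2], hf[3], bias = FALSE), layer_bn(hf[3]), layer_lrelu(s), layer_maxpool(),
        layer_adapool(9L),
        layer_conv(1L, hf[3], 10L, bias = FALSE), layer_bn(10L), layer_lrelu(s)
      ),
      ext = list(
        layer_local(k, 9L, 20L, ef[1]), layer_lrelu(s),
        layer_local(k, w1, ef[1], ef[2]), layer_lrelu(s),
        layer_flatten()
      ),
      head_r = list(layer_dense(w2 * ef[2], hh), layer_lrelu(s), layer_dense(hh, 1L)),
      head_c = list(layer_dense(w2 * ef[2], hh), layer_lrelu(s), layer_dense(hh, 1L))
    )
  })
  structure(list(config = config, stacks = net), class = "panbinder_network")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

check_tensor <- function(x, width, channels, what) {
  if (!is.array(x) || length(dim(x)) != 3L ||
      dim(x)[2] != width || dim(x)[3] != channels) {
    abort(sprintf("%s must be an array of shape N x %d x %d", what, width, channels),
          class = "panbinder_shape_error")
  }
}

# Batched forward pass. pep: (N,9,20); hla_unique: (U,372,21); hla_of: length-N
# integer index into the U unique HLA rows (the HLA encoder runs once per
# unique allele and its output rows are replicated, which is exact for
# inference and defines the batch statistics seen by the HLA batch-norm
# layers during training). Returns predictions, the context matrix and, when
# `keep_caches`, everything backprop needs.
nn_forward <- function(net, pep, hla_unique, hla_of, training = FALSE,
                       keep_caches = FALSE) {
  check_tensor(pep, 9L, 20L, "peptide tensor batch")
  check_tensor(hla_unique, HLA_WIDTH, GAP_CHANNEL, "HLA tensor batch")
  st <- net$stacks
  n <- dim(pep)[1]

  fp <- stack_forward(st$pep, pep, training)
  fh <- stack_forward(st$hla, hla_unique, training)
  hrep <- fh$out[hla_of, , , drop = FALSE]
  concat <- array(0, c(n, 9L, 20L))
  concat[, , 1:10] <- fp$out
  concat[, , 11:20] <- hrep
  fe <- stack_forward(st$ext, concat, training)
  fr <- stack_forward(st$head_r, fe$out, training)
  fc <- stack_forward(st$head_c, fe$out, training)

  z <- as.numeric(fc$out)
  out <- list(
    log_ic50_pred = as.numeric(fr$out),
    binding_prob = sigmoid(z),
    context = fe$out
  )
  if (training) {
    st$pep <- fp$layers; st$hla <- fh$layers; st$ext <- fe$layers
    st$head_r <- fr$layers; st$head_c <- fc$layers
    net$stacks <- st
  }
  if (keep_caches) {
    out$net <- net
    out$caches <- list(pep = fp$caches, hla = fh$caches, ext = fe$caches,
                       head_r = fr$caches, head_c = fc$caches)
    out$hla_of <- hla_of
    out$n_unique <- dim(hla_unique)[1]
  }
  out
}

# Backward pass: dy_r = dL/d(log_ic50_pred), dz_c = dL/d(pre-sigmoid logit)
nn_backward <- function(net, fw, dy_r, dz_c) {
  st <- net$stacks
  n <- length(dy_r)
  br <- stack_backward(st$head_r, fw$caches$head_r, matrix(dy_r, n, 1L))
  bc <- stack_backward(st$head_c, fw$caches$head_c, matrix(dz_c, n, 1L))
  be <- stack_backward(st$ext, fw$caches$ext, br$dx + bc$dx)
  dpep <- be$dx[, , 1:10, drop = FALSE]
  dhla_rep <- be$dx[, , 11:20, drop = FALSE]
  # pool replicated HLA gradients back onto the unique allele rows
  dim(dhla_rep) <- c(n, 90L)
  dhla_u <- rowsum(dhla_rep, group = fw$hla_of, reorder = TRUE)
  full <- matrix(0, fw$n_unique, 90L)
  full[as.integer(rownames(dhla_u)), ] <- dhla_u
  dim(full) <- c(fw$n_unique, 9L, 10L)
  bp <- stack_backward(st$pep, fw$caches$pep, dpep, need_dx = FALSE)
  bh <- stack_backward(st$hla, fw$caches$hla, full, need_dx = FALSE)
  list(pep = bp$grads, hla = bh$grads, ext = be$grads,
       head_r = br$grads, head_c = bc$grads)
}

#' Forward pass for a single peptide–HLA pair
#'
#' Runs one encoded pair through the network in inference mode and returns
#' the dual prediction and the binding context vector. For batch prediction
#' over a sample table use [predict.panbinder_network()].
#'
#' @param net A `panbinder_network` (or the network inside a fitted model).
#' @param peptide_tensor A 1 x 9 x 20 array from [encode_peptide()].
#' @param hla_tensor A 1 x 372 x 21 array from [encode_hla()].
#' @return A list with `log_ic50_pred`, `binding_prob` (in \[0, 1\]) and
#'   `context` (numeric vector of length 2560).
#' @export
network_forward <- function(net, peptide_tensor, hla_tensor) {
  stopifnot(inherits(net, "panbinder_network"))
  fw <- nn_forward(net, peptide_tensor, hla_tensor, hla_of = 1L)
  list(log_ic50_pred = fw$log_ic50_pred,
       binding_prob = fw$binding_prob,
       context = as.numeric(fw$context))
}

#' Apply a locally connected layer
#'
#' A locally connected layer is a valid-padding convolution whose kernel
#' weights differ at every output position: output position `i` depends only
#' on input positions `i .. i+k-1` through the `i`-th weight block. With all
#' position blocks tied to the same kernel it reduces exactly to a standard
#' valid convolution.
#'
#' @param weights A list with `W`, an array of shape
#'   `(k * C_in, C_out, W_out)` holding one kernel block per output
#'   position, and optionally `b`, a `W_out x C_out` bias matrix.
#' @param x Input array of shape `N x W x C_in`.
#' @return Array of shape `N x (W - k + 1) x C_out`.
#' @export
locally_connected_apply <- function(weights, x) {
  stopifnot(is.list(weights), is.array(weights$W), length(dim(weights$W)) == 3L)
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort("x must be an N x W x C array", class = "panbinder_shape_error")
  }
  c_in_k <- dim(weights$W)[1]
  c_out <- dim(weights$W)[2]
  wp <- dim(weights$W)[3]
  k <- c_in_k %/% dim(x)[3]
  if (k * dim(x)[3] != c_in_k || k > dim(x)[2] || dim(x)[2] - k + 1L != wp) {
    abort("weight blocks do not match the input shape", class = "panbinder_shape_error")
  }
  layer <- list(type = "local", hyp = list(k = k, w_in = dim(x)[2]),
                par = list(W = weights$W,
                           b = weights$b %||% matrix(0, wp, c_out)))
  lay_forward(layer, x)$out
}

#' Batch prediction over a sample table
#'
#' Encodes every (peptide, allele) row, runs the network in inference mode
#' and returns the input rows augmented with the dual outputs: the predicted
#' log IC50, its back-transformed IC50 in nM (clamped to \[0, 80000\]) and
#' the predicted binding probability. Row order is preserved.
#'
#' @param object A `panbinder_network` or fitted `panbinder_fit`.
#' @param samples Tibble of binding samples (needs `allele` and `peptide`).
#' @param alleles Named character vector of aligned HLA sequences covering
#'   every allele in `samples`.
#' @param batch_size Rows per forward pass.
#' @param ... Unused.
#' @return `samples` with columns `log_ic50_pred`, `ic50_pred`,
#'   `binding_prob` appended.
#' @export
predict.panbinder_network <- function(object, samples, alleles, batch_size = 256L, ...) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L) {
    return(dplyr::mutate(as_tibble(samples),
                         log_ic50_pred = numeric(0), ic50_pred = numeric(0),
                         binding_prob = numeric(0)))
  }
  missing_alleles <- setdiff(unique(samples$allele), names(alleles))
  if (length(missing_alleles)) {
    abort(paste("alleles missing from the allele index:",
                paste(missing_alleles, collapse = ", ")),
          class = "panbinder_lookup_error")
  }
  enc <- encode_batch(samples, alleles)
  n <- nrow(samples)
  log_pred <- numeric(n)
  prob <- numeric(n)
  starts <- seq.int(1L, n, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, n)
    idx <- s:e
    sub_of <- enc$hla_of[idx]
    u <- sort(unique(sub_of))
    fw <- nn_forward(object, enc$pep[idx, , , drop = FALSE],
                     enc$hla[u, , , drop = FALSE],
                     match(sub_of, u))
    log_pred[idx] <- fw$log_ic50_pred
    prob[idx] <- fw$binding_prob
  }
  out <- as_tibble(samples)
  out$log_ic50_pred <- log_pred
  out$ic50_pred <- ic50_from_log(log_pred)
  out$binding_prob <- prob
  out
}

# Encode a sample table: peptide batch tensor, unique-allele HLA tensor and
# the per-row index into it.
encode_batch <- function(samples, alleles) {
  n <- nrow(samples)
  chars <- matrix(unlist(strsplit(toupper(samples$peptide), "", fixed = TRUE),
                         use.names = FALSE), ncol = 9L, byrow = TRUE)
  ch <- aa_channel(chars)
  if (anyNA(ch)) {
    abort("sample peptides contain non-standard characters",
          class = "panbinder_alphabet_error")
  }
  pep <- array(0, c(n, 9L, 20L))
  pep[cbind(rep(seq_len(n), 9L), rep(seq_len(9L), each = n), as.integer(ch))] <- 1
  allele_names <- unique(samples$allele)
  hla <- array(0, c(length(allele_names), HLA_WIDTH, GAP_CHANNEL))
  for (i in seq_along(allele_names)) {
    hla[i, , ] <- encode_hla(alleles[[allele_names[i]]])[1L, , ]
  }
  list(pep = pep, hla = hla, hla_of = match(samples$allele, allele_names))
}
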