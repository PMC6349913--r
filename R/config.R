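#' Read a run configuration from a YAML file
#'
#' A configuration file collects the tunable settings of a run in one
#' human-readable place: a `network` section (any argument of
#' [network_config()], e.g. `preset`, `seed`, filter counts), a `training`
#' section (any schedule argument of [train_network()]: `epochs`,
#' `batch_size`, `batch_by`, `learning_rate`, `momentum`, `min_lr`,
#' `lr_patience`, `stop_patience`, `improve_tol`, `seed`) and an `io`
#' section whose `col_map` entry translates affinity-table column names for
#' other dialects (see [read_affinity_table()]). Every section and key is
#' optional; omitted keys keep their function defaults.
#'
#' @param path Path to a YAML file.
#' @return A list of class `panbinder_settings` with elements `network` (a
#'   [network_config()]), `training` (named list of [train_network()]
#'   arguments) and `col_map` (named character vector or `NULL`).
#' @examples
#' \dontrun{
#' cfg <- read_config("run.yaml")
#' net <- build_network(cfg$network)
#' fit <- do.call(train_network,
#'                c(list(net, train, val, alleles), cfg$training))
#' }
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) {
    abort("config file must contain a YAML mapping", class = "panbinder_format_error")
  }
  net_args <- raw$network %||% list()
  unknown <- setdiff(names(net_args), names(formals(network_config)))
  if (length(unknown)) {
    abort(paste("unknown network settings:", paste(unknown, collapse = ", ")),
          class = "panbinder_format_error")
  }
  train_args <- raw$training %||% list()
  allowed <- setdiff(names(formals(train_network)),
                     c("net", "train", "val", "alleles", "verbose"))
  unknown <- setdiff(names(train_args), allowed)
  if (length(unknown)) {
    abort(paste("unknown training settings:", paste(unknown, collapse = ", ")),
          class = "panbinder_format_error")
  }
  col_map <- raw$io$col_map
  if (!is.null(col_map)) col_map <- unlist(col_map)
  structure(list(network = do.call(network_config, net_args),
                 training = train_args,
                 col_map = col_map),
            class = "panbinder_settings")
}

#' @export
print.panbinder_settings <- function(x, ...) {
  cat("<panbinder_settings>\n")
  print(x$network)
  if (length(x$training)) {
    cat("  training overrides:",
        paste(names(x$training), unlist(x$training), sep = "=", collapse = ", "),
        "\n")
  }
  if (length(x$col_map)) {
    cat("  column mapping:",
        paste(names(x$col_map), x$col_map, sep = " <- ", collapse = ", "), "\n")
  }
  invisible(x)
}
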