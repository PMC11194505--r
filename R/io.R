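#' Export a run to flat files
#'
#' Writes the resolved configuration (YAML), the six weight matrices and
#' the initial weights (one CSV each), the stimulus stream and history
#' tables (CSV) and a JSON sidecar with the summary quantities and
#' computation parameters into a directory.
#'
#' @param fit A fitted [hebbnet()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_config(fit$config, file.path(dir, "config.yaml"))
  write_weight_set(fit$weights, dir, prefix = "final_")
  write_weight_set(fit$weights_init, dir, prefix = "initial_")
  utils::write.csv(fit$stream, file.path(dir, "stream.csv"), row.names = FALSE)
  utils::write.csv(fit$history, file.path(dir, "history.csv"), row.names = FALSE)
  s <- summary(fit)
  side <- list(name = s$name, n_presented = s$n_presented,
               converged = s$converged, U_E = s$U_E, U_I = s$U_I,
               norm_residual = s$norm_residual, mean_rate_E = s$mean_rate_E,
               seed = fit$config$seed)
  jsonlite::write_json(side, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Write a weight set as CSV files
#'
#' One plain CSV per non-empty block, named `<prefix><block>.csv`.
#'
#' @param w A [weight_set()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `dir`, invisibly.
#' @export
write_weight_set <- function(w, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(w)) {
    if (nrow(w[[nm]]) == 0 || ncol(w[[nm]]) == 0) next
    utils::write.table(w[[nm]], file.path(dir, paste0(prefix, nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a weight set back from CSV files
#'
#' @param dir Directory written by [write_weight_set()].
#' @param dims A [network_dims()] object.
#' @param prefix File-name prefix used at write time.
#' @return A [weight_set()].
#' @export
read_weight_set <- function(dir, dims, prefix = "") {
  blocks <- c("W_EE", "W_EI", "W_EF", "W_IE", "W_II", "W_IF")
  out <- list()
  for (nm in blocks) {
    f <- file.path(dir, paste0(prefix, nm, ".csv"))
    if (file.exists(f))
      out[[nm]] <- as.matrix(utils::read.table(f, sep = ",", header = FALSE))
  }
  do.call(weight_set, c(list(dims = dims), out))
}

#' Read an input-pattern ensemble from a plain numeric CSV
#'
#' One pattern per row, one input channel per column, no header.
#'
#' @param path CSV file path.
#' @return Numeric matrix.
#' @export
read_ensemble_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}
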