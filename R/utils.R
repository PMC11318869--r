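# FNV-1a hash over the serialized object; used to stamp artifacts with the
# configuration that produced them.
nd_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  # simple 31-bit polynomial rolling hash; double precision stays exact
  # because h * 131 + 255 < 2^38 << 2^53
  h <- 17
  for (byte in as.integer(raw)) h <- (h * 131 + byte) %% 2147483647
  sprintf("%08x", h)
}

#' Write / read a simulation trace
#'
#' Stores the voltage and membrane-current matrices, somatic spike times,
#' event trains, time base, and a hash of the morphology configuration in
#' one file; the morphology itself is serialized alongside as JSON when
#' `morphology_json` is given.
#'
#' @param trace an `nd_trace`.
#' @param path file path (`.rds`).
#' @param morphology_json optional path for a JSON morphology sidecar.
#' @return `read_trace` returns the `nd_trace`.
#' @export
write_trace <- function(trace, path, morphology_json = NULL) {
  stopifnot(inherits(trace, "nd_trace"))
  if (!is.null(morphology_json))
    write_morphology(trace$morphology, morphology_json)
  attr(trace, "config_hash") <- nd_hash(list(
    morph = trace$morphology$compartments,
    dt = trace$internal_dt, record_dt = trace$record_dt,
    seed = trace$events$seed))
  saveRDS(trace, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- readRDS(path)
  stopifnot(inherits(tr, "nd_trace"))
  tr
}

#' Write / read a prepared dataset
#'
#' @param dataset an `nd_dataset`.
#' @param path file path (`.rds`).
#' @return `read_dataset` returns the `nd_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "nd_dataset"))
  attr(dataset, "config_hash") <- nd_hash(list(
    n_comp = dataset$n_comp, seed = dataset$seed,
    n_train = length(dataset$train$offsets)))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- readRDS(path)
  stopifnot(inherits(ds, "nd_dataset"))
  ds
}
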