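# Plain-text on-disk formats. Spike trains and input sequences travel as
# TSV matrices with a JSON sidecar (shape, dt_label, seed, ground truth);
# expression fixtures as MatrixMarket + CSV labels; configs as YAML. All
# formats are plain text so fixtures diff cleanly and digest stably.

#' Read and write spike trains
#'
#' A spike train (or real-valued trace) is stored as a headerless
#' tab-separated `[rows x T]` matrix next to a JSON sidecar
#' (`<path>.json`) holding the shape, the nominal step duration and any
#' generator ground truth.
#'
#' @param x A [spike_train] or numeric matrix.
#' @param path Output file (e.g. `spikes.tsv`).
#' @param sidecar Optional list serialized to `<path>.json`.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   matrix with the sidecar (if present) attached as attribute `sidecar`;
#'   `read_spike_train` additionally classes the result as [spike_train].
#' @export
write_trace <- function(x, path, sidecar = NULL) {
  m <- if (inherits(x, "spike_train")) unclass(x) else x
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- c(list(nrow = nrow(m), ncol = ncol(m)),
            if (!is.null(attr(x, "dt_label")))
              list(dt_label = attr(x, "dt_label")),
            sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    attr(m, "sidecar") <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  }
  m
}

#' @rdname write_trace
#' @export
read_spike_train <- function(path) {
  m <- read_trace(path)
  sc <- attr(m, "sidecar")
  out <- spike_train(m, dt_label = sc$dt_label)
  attr(out, "sidecar") <- sc
  out
}

#' Write an expression fixture as MatrixMarket plus labels
#'
#' @param counts `[cells x genes]` count matrix.
#' @param labels Label vector (one per cell).
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly. Files: `counts.mtx`, `labels.csv`,
#'   `genes.csv`, `cells.csv`.
#' @export
write_expression <- function(counts, labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  utils::write.csv(data.frame(cell = seq_len(nrow(counts)), label = labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(gene = paste0("g", seq_len(ncol(counts)))),
                   file.path(dir, "genes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell = paste0("c", seq_len(nrow(counts)))),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression
#' @export
read_expression <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  labels <- utils::read.csv(file.path(dir, "labels.csv"))$label
  list(counts = counts, labels = labels)
}

#' Run manifest
#'
#' Every command-line-style run emits a manifest: the resolved
#' configuration, the seed, the package version, digests of the inputs and
#' the output paths. A run is exactly reproducible from its manifest (see
#' [run_from_manifest]).
#'
#' @param command Subcommand name.
#' @param config Resolved configuration list.
#' @param seed Integer seed.
#' @param inputs Named character vector/list of input paths to digest.
#' @param outputs Named list of output paths.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(command, config, seed, inputs = list(),
                         outputs = list()) {
  digests <- lapply(inputs, function(p) {
    if (file.exists(p)) file_digest(p) else NA_character_
  })
  structure(list(
    command = command,
    config = config,
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("hetsnn")),
    input_digests = digests,
    outputs = outputs,
    wall_clock = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    class = "run_manifest")
}

# Content digest without extra dependencies: sum of a rolling polynomial
# hash over the raw bytes, hex-encoded. Stable across platforms.
file_digest <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  h <- 0
  mod <- 2^31 - 1
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 4096))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% mod
  }
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}

#' Read or write a run configuration
#'
#' Configurations are nested key-value YAML with sections `model`,
#' `encoding` and `training`; every run writes back the fully resolved copy
#' it used.
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_config` returns the list; `write_config` returns `path`.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
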