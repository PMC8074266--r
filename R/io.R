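#' Data set readers and writers
#'
#' Three plain-text on-disk layouts, each a directory with a `meta.json`
#' descriptor: `"archive"` (one TSV of stacked dense matrices, lossless
#' full-precision round trip), `"edgelist"` (one TSV per subject with
#' 0-based `node_i < node_j` pairs and weights; diagonal entries are not
#' representable and are marked unobserved on read), and `"csvdir"` (one
#' dense CSV per subject). Symmetry is validated on read; an asymmetry
#' above 1e-6 or inconsistent duplicate edge listings are errors.
#'
#' @param dataset an [adjacency_dataset()].
#' @param path directory to create.
#' @param format one of `"archive"`, `"edgelist"`, `"csvdir"`.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   an [adjacency_dataset()].
#' @export
write_dataset <- function(dataset, path, format = c("archive", "edgelist",
                                                    "csvdir")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- n_nodes(dataset); N <- n_subjects(dataset)
  meta <- list(format = format, n = n, N = N,
               has_mask = !is.null(dataset$mask))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  if (!is.null(dataset$mask))
    write.table(dataset$mask * 1L, file.path(path, "mask.tsv"), sep = "\t",
                row.names = FALSE, col.names = FALSE)
  fmt <- function(M) apply(M, 2, function(col) sprintf("%.17g", col))
  if (format == "archive") {
    con <- file(file.path(path, "matrices.tsv"), "w")
    on.exit(close(con))
    for (k in seq_len(N))
      writeLines(apply(fmt(dataset$A[, , k]), 1, paste, collapse = "\t"), con)
  } else if (format == "edgelist") {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    for (k in seq_len(N)) {
      df <- data.frame(node_i = ut[, 1] - 1L, node_j = ut[, 2] - 1L,
                       weight = sprintf("%.17g", dataset$A[, , k][ut]))
      write.table(df, file.path(path, sprintf("subject_%04d.tsv", k)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  } else {
    for (k in seq_len(N))
      write.table(fmt(dataset$A[, , k]),
                  file.path(path, sprintf("subject_%04d.csv", k)), sep = ",",
                  row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("not a data set directory: ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  n <- meta$n; N <- meta$N
  mask <- NULL
  if (isTRUE(meta$has_mask))
    mask <- as.matrix(read.table(file.path(path, "mask.tsv"))) > 0
  A <- array(0, c(n, n, N))
  if (meta$format == "archive") {
    M <- as.matrix(read.table(file.path(path, "matrices.tsv"), sep = "\t",
                              colClasses = "numeric"))
    if (nrow(M) != n * N || ncol(M) != n) stop("malformed archive matrix block")
    for (k in seq_len(N)) A[, , k] <- M[(k - 1) * n + seq_len(n), ]
  } else if (meta$format == "edgelist") {
    for (k in seq_len(N)) {
      df <- read.table(file.path(path, sprintf("subject_%04d.tsv", k)),
                       header = TRUE, sep = "\t")
      if (any(df$node_i < 0 | df$node_j < 0 | df$node_i >= n | df$node_j >= n))
        stop("edge list node index out of range in subject ", k)
      if (any(df$node_i == df$node_j))
        stop("diagonal entries are not allowed in edge lists (subject ", k, ")")
      key <- paste(pmin(df$node_i, df$node_j), pmax(df$node_i, df$node_j))
      if (anyDuplicated(key)) {
        dup <- key[duplicated(key)]
        w <- tapply(df$weight, key, function(x) diff(range(x)))
        if (any(w[dup] > 1e-6 * pmax(1, abs(tapply(df$weight, key, max)[dup]))))
          stop("edge pair listed twice with inconsistent weights (subject ",
               k, ")")
        df <- df[!duplicated(key), ]
      }
      M <- matrix(0, n, n)
      M[cbind(df$node_i + 1L, df$node_j + 1L)] <- df$weight
      M[cbind(df$node_j + 1L, df$node_i + 1L)] <- df$weight
      A[, , k] <- M
    }
    if (is.null(mask)) {
      mask <- matrix(TRUE, n, n)
      diag(mask) <- FALSE
    }
  } else if (meta$format == "csvdir") {
    for (k in seq_len(N)) {
      M <- as.matrix(read.table(file.path(path, sprintf("subject_%04d.csv", k)),
                                sep = ","))
      if (!all(dim(M) == n)) stop("inconsistent matrix dimension in subject ", k)
      if (max(abs(M - t(M))) > 1e-6) stop("asymmetric matrix in subject ", k)
      A[, , k] <- (M + t(M)) / 2
    }
  } else stop("unknown format: ", meta$format)
  adjacency_dataset(A, mask = mask)
}

#' Model parameter serialization
#'
#' A single JSON file holding `F` (row-major), `mu`, the two standard
#' deviations, the dimensions, the mask convention, and free-form metadata
#' (seed, iteration count, ...).
#'
#' @param params a [model_params()] object.
#' @param path file path.
#' @param meta named list of metadata to store alongside.
#' @export
write_model_params <- function(params, path, meta = list()) {
  obj <- list(n = nrow(params$F), p = ncol(params$F),
              F = params$F,  # serialized row-major as nested arrays
              mu = params$mu, sigma_lambda = params$sigma_lambda,
              sigma_eps = params$sigma_eps, meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  F <- if (is.matrix(obj$F)) obj$F else matrix(unlist(obj$F), obj$n, obj$p,
                                               byrow = TRUE)
  params <- model_params(F, obj$mu, obj$sigma_lambda, obj$sigma_eps)
  attr(params, "meta") <- obj$meta
  params
}
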