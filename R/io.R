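#' Read and write graph collections as plain text
#'
#' Two on-disk layouts are supported for collections of simple undirected
#' graphs on a common aligned vertex set:
#' * dense 0/1 CSV, one file per graph, with a header row of 0-based
#'   vertex ids;
#' * a single 3-column edge-list TSV with columns `u`, `v`, `graph_index`
#'   (all 0-based, each undirected edge stored once with `u < v`).
#'
#' @param G a `graph_collection`.
#' @param dir directory for dense CSV files (one `graph_<k>.csv` each).
#' @param file path of the edge-list TSV.
#' @param n vertex count (required when reading an edge list, since
#'   isolated top-index vertices are not recoverable from edges alone).
#' @return The written paths, or the `graph_collection` read back.
#' @name graph_io
NULL

#' @rdname graph_io
#' @export
write_adjacency_csv <- function(G, dir) {
  graphs <- if (inherits(G, "graph_collection")) G$graphs else G
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(graphs))
  ids <- seq_len(nrow(graphs[[1]])) - 1L
  for (k in seq_along(graphs)) {
    paths[k] <- file.path(dir, sprintf("graph_%03d.csv", k))
    A <- graphs[[k]]
    colnames(A) <- ids
    utils::write.csv(A, paths[k], row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname graph_io
#' @export
read_adjacency_csv <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(paths) == 0) stop("no .csv files in ", dir)
  graphs <- lapply(paths, function(p) {
    A <- as.matrix(utils::read.csv(p, check.names = FALSE))
    dimnames(A) <- NULL
    A
  })
  graph_collection(graphs)
}

#' @rdname graph_io
#' @export
write_edgelist_tsv <- function(G, file) {
  graphs <- if (inherits(G, "graph_collection")) G$graphs else G
  rows <- list()
  for (k in seq_along(graphs)) {
    idx <- which(upper.tri(graphs[[k]]) & graphs[[k]] == 1, arr.ind = TRUE)
    rows[[k]] <- data.frame(u = idx[, 1] - 1L, v = idx[, 2] - 1L,
                            graph_index = k - 1L)
  }
  utils::write.table(do.call(rbind, rows), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname graph_io
#' @export
read_edgelist_tsv <- function(file, n) {
  df <- utils::read.delim(file)
  if (!all(c("u", "v", "graph_index") %in% names(df))) {
    stop("edge list must have columns u, v, graph_index")
  }
  m <- max(df$graph_index) + 1L
  graphs <- lapply(seq_len(m) - 1L, function(k) {
    A <- matrix(0, n, n)
    e <- df[df$graph_index == k, , drop = FALSE]
    A[cbind(e$u + 1L, e$v + 1L)] <- 1
    A + t(A)
  })
  graph_collection(graphs)
}

#' Sample a graph collection from a model configuration
#'
#' Model configurations are JSON or YAML with fields
#' `gram_matrix` (or `atoms` + `weights`), `n`, `model`
#' (`iid` / `forward` / `generator` / `pair`), the model parameter
#' (`m`, `rho_steps`, `nu` or `rho`) and `seed`.
#'
#' @param config a list, or path to a `.json` / `.yaml` file.
#' @return A `graph_collection`.
#' @export
sample_from_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  F <- if (!is.null(config$gram_matrix)) {
    sbm_mixture(matrix(unlist(config$gram_matrix),
                       nrow = sqrt(length(unlist(config$gram_matrix)))),
                config$weights)
  } else {
    atoms <- config$atoms
    if (is.list(atoms)) atoms <- do.call(rbind, lapply(atoms, unlist))
    latent_mixture(as.matrix(atoms), config$weights)
  }
  X <- sample_latent(F, config$n, seed = config$seed,
                     balanced = isTRUE(config$balanced))
  switch(config$model,
    iid = sample_iid_collection(X, config$m, seed = config$seed),
    forward = sample_forward_chain(X, unlist(config$rho_steps),
                                   seed = config$seed),
    generator = sample_generator_collection(X, unlist(config$nu),
                                            seed = config$seed),
    pair = sample_correlated_pair(X, config$rho, seed = config$seed),
    stop("unknown model: ", config$model)
  )
}
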