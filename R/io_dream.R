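#' Construct an expression dataset
#'
#' Container for a DREAM-style expression compendium: an ordered gene list,
#' zero or more time-series matrices (time points x genes) and an optional
#' matrix of steady-state condition profiles (profiles x genes) with
#' per-profile labels such as `"wt"` or `"ko:G5"`.
#'
#' @param gene_names Character vector, canonical gene order.
#' @param timeseries List of numeric matrices, each `T x N` with `T >= 2`.
#' @param conditions Numeric matrix `M x N`, or `NULL`.
#' @param condition_labels Character vector of length `M`, or `NULL`.
#' @param provenance Free-text source tag.
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(gene_names, timeseries = list(),
                               conditions = NULL, condition_labels = NULL,
                               provenance = "unknown") {
  gene_names <- as.character(gene_names)
  n <- length(gene_names)
  if (n == 0L) stop("dataset must contain at least one gene", call. = FALSE)
  if (anyDuplicated(gene_names)) {
    stop("duplicated gene names", call. = FALSE)
  }
  timeseries <- lapply(timeseries, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != n) abort_dim("time-series matrix does not match gene count")
    if (nrow(m) < 2L) stop("time series needs T >= 2", call. = FALSE)
    colnames(m) <- gene_names
    storage.mode(m) <- "double"
    m
  })
  if (!is.null(conditions)) {
    conditions <- as.matrix(conditions)
    if (ncol(conditions) != n) {
      abort_dim("condition matrix does not match gene count")
    }
    colnames(conditions) <- gene_names
    storage.mode(conditions) <- "double"
    if (is.null(condition_labels)) {
      condition_labels <- rep("unlabeled", nrow(conditions))
    }
    if (length(condition_labels) != nrow(conditions)) {
      abort_dim("one label per condition profile required")
    }
  }
  ds <- structure(
    list(gene_names = gene_names, timeseries = timeseries,
         conditions = conditions, condition_labels = condition_labels,
         provenance = provenance),
    class = "ExpressionDataset")
  impute_missing(ds)
}

# Per-gene mean imputation within each matrix; count is messaged, matching
# the policy that no NaN survives loading.
impute_missing <- function(ds) {
  n_imputed <- 0L
  fix <- function(m) {
    bad <- !is.finite(m)
    if (any(bad)) {
      n_imputed <<- n_imputed + sum(bad)
      for (j in seq_len(ncol(m))) {
        col <- m[, j]
        miss <- !is.finite(col)
        if (any(miss)) {
          mu <- mean(col[!miss])
          if (!is.finite(mu)) mu <- 0
          m[miss, j] <- mu
        }
      }
    }
    m
  }
  ds$timeseries <- lapply(ds$timeseries, fix)
  if (!is.null(ds$conditions)) ds$conditions <- fix(ds$conditions)
  if (n_imputed > 0L) {
    message("imputed ", n_imputed, " missing value(s) with per-gene means")
  }
  ds
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", length(x$gene_names), "genes;",
      length(x$timeseries), "time series",
      if (length(x$timeseries) > 0L) {
        paste0("(T = ", paste(unique(vapply(x$timeseries, nrow, 1L)),
                              collapse = "/"), ")")
      } else "",
      ";", if (is.null(x$conditions)) 0L else nrow(x$conditions),
      "condition profiles [", x$provenance, "]\n")
  invisible(x)
}

#' Construct a directed regulatory network
#'
#' Directed gene graph with gold-standard edges. Self-loops are rejected,
#' duplicate edges collapsed, and every endpoint must appear in `node_ids`.
#' Known negatives (pairs curated as non-interacting) travel alongside the
#' positive edges.
#'
#' @param node_ids Character vector, canonical gene order.
#' @param edges Two-column character matrix (regulator, target); may have
#'   zero rows.
#' @param known_negatives Optional two-column character matrix of curated
#'   non-edges.
#' @return An object of class `RegulatoryNetwork` with fields `node_ids`,
#'   `edges`, `edge_index` (two-column integer matrix, 1-based into
#'   `node_ids`) and `known_negatives`.
#' @export
regulatory_network <- function(node_ids, edges,
                               known_negatives = NULL) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("duplicated node ids", call. = FALSE)
  edges <- normalize_edge_matrix(edges)
  check_pairs <- function(p, what) {
    if (nrow(p) == 0L) return(p)
    unknown <- setdiff(c(p[, 1L], p[, 2L]), node_ids)
    if (length(unknown) > 0L) {
      stop("unknown gene(s) in ", what, ": ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
    if (any(p[, 1L] == p[, 2L])) {
      stop("self-loop rejected in ", what, call. = FALSE)
    }
    p[!duplicated(paste(p[, 1L], p[, 2L])), , drop = FALSE]
  }
  edges <- check_pairs(edges, "edges")
  known_negatives <- check_pairs(normalize_edge_matrix(known_negatives),
                                 "known negatives")
  both <- intersect(paste(edges[, 1L], edges[, 2L]),
                    paste(known_negatives[, 1L], known_negatives[, 2L]))
  if (length(both) > 0L) {
    stop("contradictory labels for pair(s): ",
         paste(utils::head(both, 3L), collapse = "; "), call. = FALSE)
  }
  edge_index <- cbind(src = match(edges[, 1L], node_ids),
                      dst = match(edges[, 2L], node_ids))
  structure(list(node_ids = node_ids, edges = edges,
                 edge_index = edge_index,
                 known_negatives = known_negatives),
            class = "RegulatoryNetwork")
}

normalize_edge_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("regulator", "target"))))
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) abort_dim("edge matrix must have two columns")
  dimnames(x) <- list(NULL, c("regulator", "target"))
  x
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat("RegulatoryNetwork:", length(x$node_ids), "genes,",
      nrow(x$edges), "directed edges,",
      nrow(x$known_negatives), "known negatives\n")
  invisible(x)
}

#' Read a DREAM-style expression table
#'
#' Expression tables are tab-delimited with a header row of gene names and
#' one row per expression profile. `layout_spec` declares how rows are
#' interpreted: `type = "timeseries"` segments rows into consecutive series
#' of `series_length` time points each (no auto-detection); `type =
#' "conditions"` treats every row as a steady-state profile, optionally
#' labelled.
#'
#' @param path Path to a TSV file.
#' @param layout_spec List with `type` (`"timeseries"` or `"conditions"`),
#'   `series_length` (time-series only) and optional `labels` (conditions
#'   only, one per row).
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, layout_spec) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("format error: empty expression table ", path, call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  header <- trimws(header)
  if (length(header) == 0L || any(!nzchar(header)) ||
      !any(is.na(suppressWarnings(as.numeric(header))))) {
    stop("format error: missing gene-name header in ", path, call. = FALSE)
  }
  n <- length(header)
  body <- lines[-1L]
  if (length(body) == 0L) {
    stop("format error: no data rows in ", path, call. = FALSE)
  }
  rows <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != n)) {
    stop("format error: ragged row ", which(widths != n)[1L] + 1L,
         " in ", path, call. = FALSE)
  }
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(n)))
  mat <- t(vals)   # profiles x genes
  bad <- which(is.na(mat) & t(vapply(rows, function(r) {
    !(trimws(r) %in% c("NA", "NaN", "", "nan"))
  }, logical(n))), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("parse error: non-numeric cell at row ", bad[1L, 1L] + 1L,
         ", column ", bad[1L, 2L], " (", header[bad[1L, 2L]], ")",
         call. = FALSE)
  }
  type <- layout_spec$type %||% stop("layout_spec$type required")
  if (type == "timeseries") {
    len <- layout_spec$series_length %||%
      stop("layout_spec$series_length required for time-series layout")
    len <- as.integer(len)
    if (nrow(mat) %% len != 0L) {
      stop("format error: ", nrow(mat), " rows not divisible by series ",
           "length ", len, call. = FALSE)
    }
    k <- nrow(mat) %/% len
    series <- lapply(seq_len(k), function(i) {
      mat[((i - 1L) * len + 1L):(i * len), , drop = FALSE]
    })
    expression_dataset(header, timeseries = series,
                       provenance = basename(path))
  } else if (type == "conditions") {
    labels <- layout_spec$labels
    expression_dataset(header, conditions = mat,
                       condition_labels = labels,
                       provenance = basename(path))
  } else {
    stop("unknown layout type: ", type, call. = FALSE)
  }
}

#' Write an expression dataset's matrices as DREAM-style tables
#'
#' @param mat Profiles-by-genes numeric matrix with gene names as colnames.
#' @param path Output path.
#' @export
write_expression_table <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(mat), collapse = "\t"), con)
  writeLines(apply(mat, 1L, function(r) {
    paste(sprintf("%.6g", r), collapse = "\t")
  }), con)
  invisible(path)
}

#' Read a gold-standard edge list
#'
#' Lines are `regulator<TAB>target<TAB>label` with label in `{0, 1}`; the
#' label column is optional (absent means 1). Label-1 lines become directed
#' edges; label-0 lines are retained as known negatives.
#'
#' @param path Path to the edge-list file.
#' @param node_ids Canonical gene order; unknown names are rejected.
#' @return A [regulatory_network()].
#' @export
read_gold_standard <- function(path, node_ids) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pos <- neg <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "[\t ]+")[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 2L || length(f) > 3L) {
      stop("format error at line ", i, ": expected 2 or 3 fields",
           call. = FALSE)
    }
    label <- if (length(f) == 3L) f[[3L]] else "1"
    if (!label %in% c("0", "1")) {
      stop("format error at line ", i, ": label must be 0 or 1",
           call. = FALSE)
    }
    if (label == "1") pos[[length(pos) + 1L]] <- f[1:2]
    else neg[[length(neg) + 1L]] <- f[1:2]
  }
  regulatory_network(
    node_ids,
    edges = if (length(pos)) do.call(rbind, pos) else NULL,
    known_negatives = if (length(neg)) do.call(rbind, neg) else NULL)
}

#' Write a gold-standard edge list
#'
#' @param network A [regulatory_network()].
#' @param path Output path.
#' @export
write_gold_standard <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(network$edges) > 0L) {
    writeLines(paste(network$edges[, 1L], network$edges[, 2L], "1",
                     sep = "\t"), con)
  }
  if (nrow(network$known_negatives) > 0L) {
    writeLines(paste(network$known_negatives[, 1L],
                     network$known_negatives[, 2L], "0", sep = "\t"), con)
  }
  invisible(path)
}

#' Ranked regulatory-edge predictions
#'
#' Orders candidate pairs by raw score descending, breaking ties
#' lexicographically by (regulator, target) so Top-k metrics and written
#' files are reproducible. Probabilities are the sigmoid of the raw score.
#'
#' @param regulator,target Character vectors of equal length.
#' @param raw_score Numeric vector of classifier scores.
#' @return Object of class `RankedPredictions`: a data.frame with columns
#'   `regulator`, `target`, `probability`, `raw_score`.
#' @export
ranked_predictions <- function(regulator, target, raw_score) {
  stopifnot(length(regulator) == length(target),
            length(target) == length(raw_score))
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   probability = sigmoid(raw_score),
                   raw_score = as.numeric(raw_score),
                   stringsAsFactors = FALSE)
  ord <- order(-df$raw_score, df$regulator, df$target, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("RankedPredictions", "data.frame")
  df
}

#' Write ranked predictions to a TSV file
#'
#' Columns: regulator, target, probability, raw_score; rows sorted by score
#' descending with lexicographic tie-breaking, so output is byte-identical
#' across runs.
#'
#' @param preds A [ranked_predictions()] object.
#' @param path Output path.
#' @export
write_ranked_predictions <- function(preds, path) {
  stopifnot(inherits(preds, "RankedPredictions"))
  if (nrow(preds) == 0L) stop("no predictions to write", call. = FALSE)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines("regulator\ttarget\tprobability\traw_score", con)
  writeLines(sprintf("%s\t%s\t%.10g\t%.10g", preds$regulator, preds$target,
                     preds$probability, preds$raw_score), con)
  invisible(path)
}

#' @rdname write_ranked_predictions
#' @export
read_ranked_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ranked_predictions(df$regulator, df$target, df$raw_score)
}
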