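#' Expression matrix container
#'
#' Thin container for a continuous feature matrix with explicit orientation.
#' Internally values are stored features-in-rows (the dominant expression
#' dialect, genes x samples); the constructor transposes samples-in-rows
#' input.
#'
#' @param values Numeric matrix.
#' @param feature_ids,sample_ids Unique identifier vectors.
#' @param orientation Orientation of `values`: `"features_in_rows"` or
#'   `"samples_in_rows"`.
#' @return Object of class `expression_matrix` with fields `values`
#'   (features x samples), `feature_ids`, `sample_ids`.
#' @export
expression_matrix <- function(values, feature_ids = NULL, sample_ids = NULL,
                              orientation = c("features_in_rows",
                                              "samples_in_rows")) {
  orientation <- match.arg(orientation)
  values <- as.matrix(values)
  if (orientation == "samples_in_rows") values <- t(values)
  if (is.null(feature_ids)) feature_ids <- rownames(values)
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths inconsistent with matrix dimensions")
  dimnames(values) <- NULL
  structure(
    list(values = values, feature_ids = as.character(feature_ids),
         sample_ids = as.character(sample_ids)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression matrix:", length(x$feature_ids), "features x",
      length(x$sample_ids), "samples\n")
  invisible(x)
}

#' Read a feature matrix from TSV/CSV
#'
#' Expects a header row and a leading id column. The delimiter is taken from
#' the file extension (`.csv` means comma, anything else tab) unless given.
#' Non-numeric or missing cells are rejected with the offending row and
#' column named; duplicate ids and ragged rows are errors.
#'
#' @param path File path.
#' @param orientation Whether rows are features (default) or samples.
#' @param sep Field delimiter; inferred from the extension when `NULL`.
#' @return An `expression_matrix`.
#' @export
read_matrix <- function(path, orientation = c("features_in_rows",
                                              "samples_in_rows"),
                        sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file needs a header row and data rows")
  cells <- strsplit(lines, sep, fixed = TRUE)
  ncol_expect <- length(cells[[1L]])
  ragged <- which(vapply(cells, length, integer(1)) != ncol_expect)
  if (length(ragged) > 0L)
    stop("ragged row(s) at line ", paste(utils::head(ragged, 3), collapse = ", "))
  header <- cells[[1L]][-1L]
  body <- cells[-1L]
  row_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = ncol_expect - 1L)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop("non-numeric cell at row '", row_ids[i], "', column '",
           header[bad[1L]], "' (value '", body[[i]][bad[1L] + 1L], "')")
    vals[i, ] <- v
  }
  if (orientation == "features_in_rows")
    expression_matrix(vals, feature_ids = row_ids, sample_ids = header)
  else
    expression_matrix(t(vals), feature_ids = header, sample_ids = row_ids)
}

#' Write a feature matrix as TSV
#'
#' @param m An `expression_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(feature_id = m$feature_ids, m$values,
                   check.names = FALSE)
  colnames(df) <- c("feature_id", m$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample log and trimmed standardization
#'
#' The array preprocessing used before screening: each sample's values are
#' log-transformed, then centred and scaled by the trimmed mean and trimmed
#' standard deviation of that sample's log-values, discarding the lowest and
#' highest `trim_fraction` of values (default 5% each tail; the sd uses the
#' same trimmed subset as the mean). With `trim_fraction = 0` this is
#' ordinary per-sample standardization of the logs.
#'
#' @param m An `expression_matrix` with all values > 0 (log step). Data with
#'   zeros or negatives must be offset explicitly by the caller first.
#' @param trim_fraction Fraction trimmed from each tail, in `[0, 0.5)`.
#' @return A normalized `expression_matrix`.
#' @export
normalize_expression <- function(m, trim_fraction = 0.05) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!(trim_fraction >= 0 && trim_fraction < 0.5))
    stop("trim_fraction must be in [0, 0.5)")
  if (any(m$values <= 0))
    stop("normalization log-transforms the data, which requires all values ",
         "> 0; add an explicit offset first")
  lv <- log(m$values)
  norm <- apply(lv, 2L, function(x) {
    s <- sort(x)
    kcut <- floor(trim_fraction * length(x))
    kept <- if (kcut > 0) s[(kcut + 1):(length(x) - kcut)] else s
    (x - mean(kept)) / sd(kept)
  })
  expression_matrix(norm, feature_ids = m$feature_ids,
                    sample_ids = m$sample_ids)
}

# Per-feature statistics and z-values for one method over an N x p sample
# matrix. The edge-count branch uses the compiled per-column 1-D k-MST
# engine; "stat" is S (edge count), t (welch) or z_mi (mi).
compute_method_z <- function(X, labels, method = c("edgecount", "welch", "mi"),
                             k = 3L, mode = c("auto", "asymptotic",
                                              "permutation"),
                             B = 1000L, seed = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  labels <- as_group_labels(labels)
  N <- nrow(X)
  if (N != labels$N) stop("sample count does not match labels")
  if (method == "edgecount") {
    if (mode == "auto")
      mode <- if (min(labels$n) <= 10L) "permutation" else "asymptotic"
    if (mode == "permutation") {
      res <- lapply(seq_len(ncol(X)), function(i) {
        si <- if (is.null(seed)) NULL else (seed + 1000003 * i) %% 2147483647
        edge_count_test(X[, i], labels, k = k, mode = "permutation", B = B,
                        seed = si)
      })
      S <- vapply(res, `[[`, numeric(1), "S")
      pval <- vapply(res, `[[`, numeric(1), "p_value")
      # permutation p-values are discrete; z from the chi-squared map of S
      # keeps ranking continuous
      z <- quantile_normalize(S, null = "chisq", df = labels$J)
      return(list(stat = S, z = z, p_value = pval, df = labels$J))
    }
    sc <- .cpp_kmst_screen_1d(X, labels$y, labels$J, as.integer(k))
    S <- edge_count_S_batch(sc$R, sc$C, sc$n_edges, labels)
    z <- quantile_normalize(S, null = "chisq", df = labels$J)
    pval <- pchisq(S, df = labels$J, lower.tail = FALSE)
    list(stat = S, z = z, p_value = pval, df = labels$J)
  } else if (method == "welch") {
    if (labels$J != 2L)
      stop("Welch's t test is a two-sample test; got J = ", labels$J)
    w <- welch_t_matrix(X, as.integer(labels$y == 2L))
    pval <- pt(w$t, df = w$df, lower.tail = FALSE)
    list(stat = w$t, z = w$z, p_value = pval, df = w$df)
  } else {
    mi <- mi_z_matrix(X, labels)
    pval <- pnorm(mi$z, lower.tail = FALSE)
    list(stat = mi$z_mi, z = mi$z, p_value = pval, df = NA_real_)
  }
}

# Vectorised quadratic statistic over features sharing labels: per feature a
# graph with |G| = n_edges and pair count C[i], within-group counts R[i, ].
edge_count_S_batch <- function(R, C, n_edges, labels) {
  N <- labels$N
  n <- labels$n
  J <- labels$J
  m <- n_edges
  ER <- m * n * (n - 1) / (N * (N - 1))
  p4 <- n * (n - 1)  # per-group factor of the disjoint-pair term
  if (J == 2L) {
    disj <- m * (m - 1) - 2 * C
    V1 <- ER[1] * (1 - ER[1]) +
      2 * C * n[1] * (n[1] - 1) * (n[1] - 2) / (N * (N - 1) * (N - 2)) +
      disj * n[1] * (n[1] - 1) * (n[1] - 2) * (n[1] - 3) /
        (N * (N - 1) * (N - 2) * (N - 3))
    V2 <- ER[2] * (1 - ER[2]) +
      2 * C * n[2] * (n[2] - 1) * (n[2] - 2) / (N * (N - 1) * (N - 2)) +
      disj * n[2] * (n[2] - 1) * (n[2] - 2) * (n[2] - 3) /
        (N * (N - 1) * (N - 2) * (N - 3))
    CV <- disj * p4[1] * p4[2] / (N * (N - 1) * (N - 2) * (N - 3)) -
      ER[1] * ER[2]
    d1 <- R[, 1] - ER[1]
    d2 <- R[, 2] - ER[2]
    det <- V1 * V2 - CV^2
    S <- (V2 * d1^2 - 2 * CV * d1 * d2 + V1 * d2^2) / det
    bad <- !is.finite(S) | det <= 0
    if (any(bad)) {
      for (i in which(bad)) {
        cov <- matrix(c(V1[i], CV[i], CV[i], V2[i]), 2L)
        S[i] <- quad_form_stat(R[i, ], list(mean = ER, cov = cov))$S
      }
    }
    pmax(S, 0)
  } else {
    vapply(seq_len(nrow(R)), function(i) {
      mom <- moments_from_counts(m, C[i], labels)
      quad_form_stat(R[i, ], mom)$S
    }, numeric(1))
  }
}

#' Screen features against a categorical outcome
#'
#' End-to-end two-step screening: per-feature test (edge-count, Welch t, or
#' mutual-information z), quantile normalization to z-values, then FDR
#' selection by Efron's dependence-adjusted procedure or Benjamini-Hochberg
#' (on the one-sided p-values `1 - pnorm(z)`).
#'
#' @param m An `expression_matrix` (or plain features x samples matrix).
#' @param labels Group memberships, one per sample, in sample order.
#' @param method One of `"edgecount"`, `"welch"` (J = 2 only), `"mi"`.
#' @param procedure `"efron"` or `"bh"`.
#' @param alpha Targeted FDR level (default 0.10).
#' @param k Number of edge-disjoint spanning trees for the edge-count test.
#' @param mode p-value mode for the edge-count test; `"auto"` switches to
#'   permutation when the smallest group has <= 10 samples.
#' @param B Permutations per feature in permutation mode.
#' @param seed Master seed; per-feature permutation streams are derived from
#'   it so results are reproducible and independent of feature order.
#' @param verbose Print graph-regularity diagnostics (|G|, C summary).
#' @return Object of class `screening_result`: a data frame `table` with
#'   per-feature `feature_id`, `statistic`, `z`, `p_value`, `selected`,
#'   plus `method`, `procedure`, `alpha`, `k`, `seed`, `threshold` (Efron's
#'   z0 or the BH p-value cutoff) and, for Efron, the dispersion `A`.
#' @examples
#' set.seed(7)
#' X <- matrix(rnorm(50 * 40), nrow = 50) # 50 features x 40 samples
#' X[1, ] <- X[1, ] + rep(c(0, 3), each = 20)
#' r <- screen_features(X, rep(c("a", "b"), each = 20), method = "edgecount")
#' head(r$table[r$table$selected, ])
#' @export
screen_features <- function(m, labels, method = c("edgecount", "welch", "mi"),
                            procedure = c("efron", "bh"), alpha = 0.10,
                            k = 3L, mode = c("auto", "asymptotic",
                                             "permutation"),
                            B = 1000L, seed = NULL, verbose = FALSE) {
  method <- match.arg(method)
  procedure <- match.arg(procedure)
  if (!inherits(m, "expression_matrix")) m <- expression_matrix(m)
  labels <- as_group_labels(labels)
  if (length(m$sample_ids) != labels$N)
    stop("sample count (", length(m$sample_ids),
         ") does not match labels (", labels$N, ")")
  X <- t(m$values)  # N x p
  if (!is.null(seed)) set.seed(seed)  # pins tie-breaks in the k-MSTs too
  res <- compute_method_z(X, labels, method = method, k = k, mode = mode,
                          B = B, seed = seed)
  usable <- is.finite(res$z)
  selected <- rep(FALSE, length(res$z))
  if (procedure == "efron") {
    fit <- efron_select(res$z[usable], alpha = alpha)
    selected[usable] <- fit$selected
    threshold <- fit$z0
    A <- fit$A
  } else {
    sel <- bh_select(pmin(pmax(res$p_value[usable], 0), 1), alpha = alpha)
    selected[usable] <- sel$selected
    threshold <- if (sel$n_selected > 0)
      max(res$p_value[usable][sel$selected]) else NA_real_
    A <- NA_real_
  }
  if (verbose && method == "edgecount") {
    message("edge-count screening: |G| = ", k, " * (N - 1) = ",
            k * (labels$N - 1), " edges per feature graph")
  }
  structure(
    list(
      table = data.frame(feature_id = m$feature_ids, statistic = res$stat,
                         z = res$z, p_value = res$p_value,
                         selected = selected, stringsAsFactors = FALSE),
      method = method, procedure = procedure, alpha = alpha, k = as.integer(k),
      seed = seed, threshold = threshold, A = A,
      n_selected = sum(selected)
    ),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening: %s + %s, alpha = %g -> %d of %d features selected\n",
              x$method, x$procedure, x$alpha, x$n_selected,
              nrow(x$table)))
  invisible(x)
}

#' Write screening results as ranked TSV
#'
#' Features ranked by z descending; header comment lines record the method,
#' procedure, alpha, k, seed and threshold so a result file is
#' self-describing.
#'
#' @param r A `screening_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(r, path) {
  stopifnot(inherits(r, "screening_result"))
  tab <- r$table[order(-ifelse(is.finite(r$table$z), r$table$z, -Inf)), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# method=", r$method),
    paste0("# procedure=", r$procedure),
    paste0("# alpha=", r$alpha),
    paste0("# k=", r$k),
    paste0("# seed=", if (is.null(r$seed)) "NA" else r$seed),
    paste0("# threshold=", format(r$threshold, digits = 10)),
    paste(c("feature_id", "statistic", "z", "p_value", "selected"),
          collapse = "\t")
  ), con)
  lines <- paste(tab$feature_id,
                 format(tab$statistic, digits = 10, trim = TRUE),
                 format(tab$z, digits = 10, trim = TRUE),
                 format(tab$p_value, digits = 10, trim = TRUE),
                 as.integer(tab$selected), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a two-column labels file
#'
#' TSV with columns `sample_id` and `group` (header required); labels are
#' returned in the order of `sample_ids` when given.
#'
#' @param path File path.
#' @param sample_ids Optional sample ordering to match against.
#' @return Character vector of group labels.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("labels file needs two columns (sample_id, group)")
  ids <- df[[1L]]
  groups <- df[[2L]]
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, ids)
    if (anyNA(idx))
      stop("labels file is missing sample(s): ",
           paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
    groups <- groups[idx]
  }
  groups
}
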