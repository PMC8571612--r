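#' Normality-driven log transform
#'
#' Applies the single preprocessing rule used before every downstream
#' analysis: a numeric column is log-transformed when its sample skewness
#' exceeds `skew_cut` or its excess kurtosis exceeds `kurt_cut` in
#' absolute value. Columns that are entirely non-positive (the depth
#' descriptors) are first flipped to magnitudes; columns still containing
#' non-positive values after that use `log(x - min(x) + 1)`, others plain
#' `log(x)`. Every decision (flip, offset, transform) is recorded so the
#' original values can be reconstructed exactly.
#'
#' @param table data.frame; non-numeric and id columns (`species`,
#'   `scenario`) pass through untouched.
#' @param skew_cut,kurt_cut decision thresholds (defaults 1 and 2).
#' @return list with `table` (transformed) and `log` (data.frame per
#'   column: `column`, `skewness`, `kurtosis`, `flipped`, `offset`,
#'   `transformed`, `constant`).
#' @export
normality_transform <- function(table, skew_cut = 1, kurt_cut = 2) {
  num <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                 c("species", "scenario"))
  logrec <- list()
  for (v in num) {
    x <- table[[v]]
    xc <- x[!is.na(x)]
    if (length(unique(xc)) <= 1) {
      logrec[[v]] <- data.frame(column = v, skewness = NA_real_,
                                kurtosis = NA_real_, flipped = FALSE,
                                offset = NA_real_, transformed = FALSE,
                                constant = TRUE)
      next
    }
    sk <- e1071::skewness(xc)
    ku <- e1071::kurtosis(xc)          # excess kurtosis
    decide <- abs(sk) > skew_cut || abs(ku) > kurt_cut
    flipped <- FALSE; offset <- NA_real_
    if (decide) {
      if (all(xc <= 0)) { x <- -x; xc <- -xc; flipped <- TRUE }
      if (any(xc <= 0)) {
        offset <- min(xc)
        table[[v]] <- log(x - offset + 1)
      } else {
        table[[v]] <- log(x)
      }
    }
    logrec[[v]] <- data.frame(column = v, skewness = sk, kurtosis = ku,
                              flipped = flipped, offset = offset,
                              transformed = decide, constant = FALSE)
  }
  list(table = table, log = do.call(rbind, c(logrec,
                                             list(make.row.names = FALSE))))
}

#' @rdname normality_transform
#' @param transformed result of `normality_transform()`.
#' @return `inverse_normality_transform` returns the original table.
#' @export
inverse_normality_transform <- function(transformed) {
  tab <- transformed$table
  rec <- transformed$log
  for (i in seq_len(nrow(rec))) {
    if (!isTRUE(rec$transformed[i])) next
    v <- rec$column[i]
    x <- exp(tab[[v]])
    if (!is.na(rec$offset[i])) x <- x - 1 + rec$offset[i]
    if (rec$flipped[i]) x <- -x
    tab[[v]] <- x
  }
  tab
}

#' Correlation-matrix principal component analysis
#'
#' Eigendecomposition of the correlation matrix of the descriptors
#' (variables standardized, appropriate because the descriptors mix km, m
#' and proportions). Axes are ordered by decreasing eigenvalue; the sign
#' of each loading column is fixed so its largest-magnitude entry is
#' positive. A singular correlation matrix is not an error: zero
#' eigenvalues are reported.
#'
#' @param table data.frame or matrix of numeric descriptors (id columns
#'   `species`/`scenario` are dropped); >= 2 variables, >= 3 complete
#'   rows.
#' @return a `pca_result`: `loadings` (variables x axes, orthonormal),
#'   `scores` (rows x axes), `proportion` and `cumulative` variance
#'   shares, `sdev`, `center`, `scale`.
#' @export
metric_pca <- function(table) {
  if (is.data.frame(table)) {
    num <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                   c("species", "scenario"))
    X <- as.matrix(table[, num, drop = FALSE])
    if (!is.null(table$species)) rownames(X) <- table$species
  } else X <- as.matrix(table)
  if (ncol(X) < 2 || nrow(X) < 3 || anyNA(X))
    stop("PCA needs >= 2 variables, >= 3 rows and no missing values")
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant descriptor column: ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X, center = ctr, scale = sds)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  val <- pmax(eg$values, 0)
  L <- eg$vectors
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(X), paste0("PC", seq_len(ncol(L))))
  scores <- Z %*% L
  names(val) <- colnames(L)
  structure(list(loadings = L, scores = scores,
                 proportion = val / sum(val),
                 cumulative = cumsum(val) / sum(val),
                 sdev = sqrt(val), center = ctr, scale = sds),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(4, length(x$proportion))
  cat("<pca_result> variance proportions:",
      paste(sprintf("%s %.3f", names(x$proportion)[seq_len(k)],
                    x$proportion[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}
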