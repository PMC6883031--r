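#' Collinearity screening of predictor columns
#'
#' Two-stage filter used before distribution modelling. First, constant
#' columns (undefined correlation) are reported and dropped. Second, while
#' any pair of remaining columns has `|Pearson r| >= cor_threshold`, the
#' later-listed column of the strongest such pair is dropped. Third,
#' variance inflation factors (`VIF = 1 / (1 - R^2)` from regressing each
#' column on all others) are computed and the highest is dropped while any
#' `VIF >= vif_threshold`, recomputing after each drop.
#'
#' @param x data frame or numeric matrix of predictor columns.
#' @param cor_threshold pairwise Pearson threshold (default 0.8).
#' @param vif_threshold variance-inflation threshold (default 10).
#' @return list with `kept` (character vector, original order) and `report`
#'   (data frame: step, column, statistic, reason).
#' @export
screen_predictors <- function(x, cor_threshold = 0.8, vif_threshold = 10) {
  x <- as.data.frame(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2L) stop("need >= 2 predictor columns")
  if (nrow(x) < 3L) stop("need >= 3 complete rows")
  report <- data.frame(step = integer(), column = character(),
                       statistic = numeric(), reason = character())
  step <- 0L
  note <- function(col, stat, why) {
    step <<- step + 1L
    report <<- rbind(report, data.frame(step = step, column = col,
                                        statistic = stat, reason = why))
  }
  keep <- names(x)
  for (nm in keep) {
    if (stats::sd(x[[nm]]) == 0) note(nm, NA_real_, "constant")
  }
  keep <- setdiff(keep, report$column)

  repeat {
    if (length(keep) < 2L) break
    r <- stats::cor(x[keep])
    diag(r) <- 0
    if (max(abs(r)) < cor_threshold) break
    hit <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1L, ]
    drop_i <- max(hit)               # later-listed column of the pair
    note(keep[drop_i], r[hit[1L], hit[2L]], "pearson")
    keep <- keep[-drop_i]
  }

  repeat {
    if (length(keep) < 2L) break
    vifs <- vapply(keep, function(nm) vif_one(x, nm, setdiff(keep, nm)),
                   numeric(1))
    if (max(vifs) < vif_threshold) break
    worst <- which.max(vifs)
    note(keep[worst], vifs[worst], "vif")
    keep <- keep[-worst]
  }
  list(kept = keep, report = report)
}

vif_one <- function(x, target, others) {
  fit <- stats::lm(stats::reformulate(others, response = target), data = x)
  r2 <- summary(fit)$r.squared
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}
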