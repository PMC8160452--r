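# Model design machinery: stratified cohort splitting, restricted cubic
# spline bases with the 5/27.5/50/72.5/95th percentile knot scheme, rank-based
# partial-correlation screening of analytes, and design matrix construction
# with the pairwise interaction policy.

#' Stratified random split of a cohort
#'
#' Partitions a cohort into sub-cohorts (by default development / validation /
#' test at 50/25/25) by stratified random sampling so every stratum retains
#' the target proportions to within one record. Default strata are completed
#' GA week crossed with sex. Strata smaller than 3 records are pooled into a
#' global lottery with a warning.
#'
#' @param cohort cohort data frame.
#' @param fractions numeric summing to 1; names become the sub-cohort names.
#' @param strata factor of length `nrow(cohort)`, or `NULL` for the default.
#' @param seed RNG seed.
#' @return named list of disjoint sub-cohorts whose union is the input.
#' @export
split_cohort <- function(cohort,
                         fractions = c(development = 0.5, validation = 0.25,
                                       test = 0.25),
                         strata = NULL, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  k <- length(fractions)
  nm <- names(fractions)
  if (is.null(nm)) nm <- paste0("subcohort", seq_len(k))
  if (is.null(strata)) {
    strata <- interaction(floor(cohort$ga_weeks), cohort$sex, drop = TRUE)
  }
  stopifnot(length(strata) == nrow(cohort))
  set.seed(seed)
  assign <- integer(nrow(cohort))
  groups <- split(seq_len(nrow(cohort)), strata)
  small <- integer(0)
  allocate <- function(idx) {
    m <- length(idx)
    idx <- idx[sample.int(m)]
    counts <- floor(m * fractions)
    rem <- m - sum(counts)
    if (rem > 0) {
      frac_part <- m * fractions - counts
      extra <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    assign[idx] <<- rep.int(seq_len(k), counts)
  }
  for (g in groups) {
    if (length(g) < 3) small <- c(small, g) else allocate(g)
  }
  if (length(small)) {
    warning(sprintf("%d record(s) in strata smaller than 3 assigned by global lottery",
                    length(small)))
    allocate(small)
  }
  out <- lapply(seq_len(k), function(j) {
    sub <- cohort[assign == j, , drop = FALSE]
    truth <- attr(cohort, "truth")
    if (!is.null(truth)) attr(sub, "truth") <- truth[assign == j, , drop = FALSE]
    attr(sub, "preprocess") <- attr(cohort, "preprocess")
    attr(sub, "ga_reporting") <- attr(cohort, "ga_reporting")
    sub
  })
  stats::setNames(out, nm)
}

#' Empirical knots for a restricted cubic spline
#'
#' @param values numeric vector with at least 20 distinct values.
#' @param percentiles knot placement percentiles (default 5th, 27.5th, 50th,
#'   72.5th and 95th).
#' @return increasing knot vector; tied knots are collapsed with a warning,
#'   and fewer than 3 distinct knots is an error.
#' @export
compute_knots <- function(values, percentiles = c(5, 27.5, 50, 72.5, 95)) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 20) {
    stop("knot_error: need at least 20 distinct values", call. = FALSE)
  }
  kn <- stats::quantile(v, percentiles / 100, type = 7, names = FALSE)
  if (anyDuplicated(kn)) {
    warning("tied knots collapsed; spline order reduced")
    kn <- unique(kn)
  }
  if (length(kn) < 3) {
    stop("knot_error: fewer than 3 distinct knots", call. = FALSE)
  }
  kn
}

#' Restricted cubic spline basis
#'
#' For knots `t_1 < ... < t_k` returns `k - 1` columns: the identity term and
#' `k - 2` nonlinear terms
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'        + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2,}
#' the standard restricted (natural) cubic construction: the fitted function
#' is linear beyond the boundary knots, and the nonlinear terms vanish
#' identically below the first knot. Missing `x` propagates to every column.
#'
#' @param x numeric vector.
#' @param knots strictly increasing, length >= 3.
#' @return matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  stopifnot(k >= 3, !is.unsorted(knots, strictly = TRUE))
  scale2 <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(NA_real_, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (pos3(x - knots[j]) -
                       pos3(x - knots[k - 1]) * (knots[k] - knots[j]) /
                       (knots[k] - knots[k - 1]) +
                       pos3(x - knots[k]) * (knots[k - 1] - knots[j]) /
                       (knots[k] - knots[k - 1])) / scale2
  }
  out
}

#' Partial Spearman screening of candidate analytes
#'
#' Scores every candidate analyte by its rank-based partial correlation with
#' gestational age, mutually adjusted for all other candidates and the
#' clinical covariates: all variables are rank-transformed, GA and the
#' candidate are residualized on the remaining variables by least squares on
#' ranks, and the residuals are correlated. Computed equivalently through the
#' precision matrix of the rank correlation matrix.
#'
#' @param cohort preprocessed cohort data frame.
#' @param candidates analyte column names to score.
#' @param adjust_for clinical covariate columns (e.g. sex, birth weight);
#'   character columns are coded numerically before ranking.
#' @param top_k how many top analytes to flag.
#' @param ga_var response column name.
#' @return data frame sorted by decreasing `|partial_rho|`, with attribute
#'   `"top_k"` holding the selected analyte names.
#' @export
partial_spearman_screen <- function(cohort, candidates,
                                    adjust_for = c("sex", "birth_weight_g"),
                                    top_k = 7, ga_var = "ga_weeks") {
  absent <- setdiff(c(candidates, adjust_for, ga_var), names(cohort))
  if (length(absent)) {
    stop(sprintf("screen_error: missing column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  num <- function(v) if (is.numeric(v)) v else as.numeric(factor(v))
  vars <- c(ga_var, candidates, adjust_for)
  m <- vapply(vars, function(v) num(cohort[[v]]), numeric(nrow(cohort)))
  ok <- stats::complete.cases(m)
  ranks <- apply(m[ok, , drop = FALSE], 2, rank)
  cm <- stats::cor(ranks)
  keep <- vars
  prec <- tryCatch(solve(cm), error = function(e) NULL)
  if (is.null(prec)) {
    # drop linearly dependent columns (keep GA and all candidates)
    qr_d <- qr(cm)
    drop_idx <- qr_d$pivot[-seq_len(qr_d$rank)]
    droppable <- intersect(keep[drop_idx], adjust_for)
    warning(sprintf("collinear adjustment column(s) dropped: %s",
                    paste(droppable, collapse = ", ")))
    keep <- setdiff(keep, droppable)
    cm <- stats::cor(ranks[, keep, drop = FALSE])
    prec <- solve(cm)
  }
  ci <- match(candidates, keep)
  gi <- match(ga_var, keep)
  rho <- -prec[gi, ci] / sqrt(prec[gi, gi] * diag(prec)[ci])
  out <- data.frame(analyte = candidates, partial_rho = as.numeric(rho),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$partial_rho)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "top_k") <- utils::head(out$analyte, top_k)
  out
}

#' Declarative model specification
#'
#' Captures the predictor structure of the three model families:
#' * Model 1 — sex, birth weight (splined) and their interaction;
#' * Model 2 — sex and analytes (top screened analytes splined), pairwise
#'   interactions;
#' * Model 3 — sex, birth weight and analytes, pairwise interactions.
#'
#' The interaction policy is: pairwise products of the scalar (pre-spline)
#' quantitative predictors, plus sex times every spline basis column; spline
#' x spline tensor products are excluded.
#'
#' @param model_id 1, 2 or 3.
#' @param quantitative quantitative predictor names (analytes and/or
#'   `birth_weight_g`), on the preprocessed scale.
#' @param splined named list mapping a subset of `quantitative` to knot
#'   vectors.
#' @param interactions any of `"pairwise_scalar"`, `"sex_by_spline"`;
#'   `character(0)` for main effects only.
#' @param top_k_splined recorded count of splined analytes (bookkeeping for
#'   panel-restricted variants).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model_id, quantitative, splined = list(),
                       interactions = c("pairwise_scalar", "sex_by_spline"),
                       top_k_splined = length(splined)) {
  stopifnot(model_id %in% 1:3)
  bad <- setdiff(names(splined), quantitative)
  if (length(bad)) {
    stop(sprintf("spec_error: splined variable(s) not in predictors: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (kn in splined) stopifnot(length(kn) >= 3, !is.unsorted(kn, strictly = TRUE))
  structure(list(model_id = model_id, quantitative = quantitative,
                 splined = splined, interactions = interactions,
                 top_k_splined = top_k_splined),
            class = "model_spec")
}

#' Restrict a model specification to an available analyte panel
#'
#' Drops quantitative predictors (and their splines and any interaction that
#' references them) that the target site does not measure. Birth weight and
#' sex are always available. The restricted model must then be retrained from
#' scratch on the derivation cohort.
#'
#' @param spec a [model_spec()].
#' @param available_panel analyte names measured at the deployment site
#'   (derived features such as `hb_ratio` count as available only when
#'   listed).
#' @return restricted `model_spec`.
#' @export
restrict_model_spec <- function(spec, available_panel) {
  keep <- intersect(spec$quantitative, c(available_panel, "birth_weight_g"))
  if (length(keep) == 0) {
    stop("spec_error: restriction leaves no predictors", call. = FALSE)
  }
  splined <- spec$splined[intersect(names(spec$splined), keep)]
  model_spec(spec$model_id, keep, splined, spec$interactions,
             top_k_splined = length(setdiff(names(splined), "birth_weight_g")))
}

#' Build the design matrix for a model specification
#'
#' Column order is deterministic: intercept, sex indicator, spline bases (in
#' spec order; the first basis column is the variable itself), remaining main
#' effects, then interaction columns (sex x spline basis, pairwise scalar
#' products, sex x non-splined scalars). Constant columns other than the
#' intercept are dropped with a warning. Every interaction column is the
#' elementwise product of its named parents.
#'
#' @param cohort preprocessed cohort data frame with a `sex` column (M/F).
#' @param spec a [model_spec()].
#' @return object of class `ga_design`: list with `values` (numeric matrix),
#'   `column_names`, and `provenance` (per-column source variables and term
#'   type: main, spline or interaction).
#' @export
build_design_matrix <- function(cohort, spec) {
  absent <- setdiff(spec$quantitative, names(cohort))
  if (length(absent)) {
    stop(sprintf("design_error: missing analyte column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(cohort)
  sex <- as.numeric(cohort$sex == "M")
  cols <- list("(Intercept)" = rep(1, n), sex = sex)
  prov <- data.frame(column = c("(Intercept)", "sex"),
                     sources = c("", "sex"),
                     type = c("main", "main"), stringsAsFactors = FALSE)
  add <- function(name, values, sources, type) {
    cols[[name]] <<- values
    prov[nrow(prov) + 1L, ] <<- c(name, sources, type)
  }
  spl_names <- names(spec$splined)
  basis_cols <- list()
  for (v in spl_names) {
    b <- rcs_basis(cohort[[v]], spec$splined[[v]])
    nb <- ncol(b)
    cn <- c(v, paste0(v, "_rcs", 2:nb))
    for (j in seq_len(nb)) {
      add(cn[j], b[, j], v, if (j == 1) "main" else "spline")
    }
    basis_cols[[v]] <- cn
  }
  scalar_main <- setdiff(spec$quantitative, spl_names)
  for (v in scalar_main) add(v, cohort[[v]], v, "main")

  if ("sex_by_spline" %in% spec$interactions) {
    for (v in spl_names) {
      for (cn in basis_cols[[v]]) {
        add(paste0("sex:", cn), sex * cols[[cn]],
            paste("sex", v, sep = ","), "interaction")
      }
    }
  }
  if ("pairwise_scalar" %in% spec$interactions) {
    q <- spec$quantitative
    if (length(q) >= 2) {
      for (i in seq_len(length(q) - 1)) {
        for (j in (i + 1):length(q)) {
          a <- q[i]; b <- q[j]
          add(paste0(a, ":", b), cols[[a]] * cols[[b]],
              paste(a, b, sep = ","), "interaction")
        }
      }
    }
    for (v in scalar_main) {
      add(paste0("sex:", v), sex * cols[[v]], paste("sex", v, sep = ","),
          "interaction")
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  const <- apply(m, 2, function(x) {
    r <- range(x, na.rm = TRUE); !all(is.finite(r)) || r[1] == r[2]
  })
  const["(Intercept)"] <- FALSE
  if (any(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(m)[const], collapse = ", ")))
    m <- m[, !const, drop = FALSE]
    prov <- prov[!const, , drop = FALSE]
  }
  structure(list(values = m, column_names = colnames(m), provenance = prov),
            class = "ga_design")
}
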