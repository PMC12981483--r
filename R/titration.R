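#' State-classification cutoffs for lambda-dynamics titration coordinates
#'
#' In lambda-dynamics constant-pH MD the titration coordinate lambda is 1 for
#' the deprotonated and 0 for the protonated form of a site; intermediate
#' values are unphysical mixing states. Residues with two titratable sites
#' (carboxylates, histidine) carry an additional tautomer-interconversion
#' coordinate chi, and frames with mixed chi are discarded from state counts.
#' This constructor bundles the four cutoffs that define "pure" frames.
#'
#' @param deprot_lambda_min lambda at or above which a frame counts as
#'   deprotonated (default 0.8).
#' @param prot_lambda_max lambda at or below which a frame counts as
#'   protonated (default 0.2).
#' @param chi_pure_low,chi_pure_high chi is "pure" when chi < `chi_pure_low`
#'   or chi > `chi_pure_high`; mixed tautomeric frames in between are
#'   discarded (defaults 0.2 and 0.8).
#' @return An object of class `state_cutoffs`.
#' @examples
#' state_cutoffs()
#' @export
state_cutoffs <- function(deprot_lambda_min = 0.8, prot_lambda_max = 0.2,
                          chi_pure_low = 0.2, chi_pure_high = 0.8) {
  stopifnot(is.numeric(deprot_lambda_min), is.numeric(prot_lambda_max),
            is.numeric(chi_pure_low), is.numeric(chi_pure_high))
  if (!(0 <= prot_lambda_max && prot_lambda_max < deprot_lambda_min &&
        deprot_lambda_min <= 1))
    stop("cutoff ordering violated: need 0 <= prot_lambda_max < deprot_lambda_min <= 1")
  if (!(0 <= chi_pure_low && chi_pure_low < chi_pure_high && chi_pure_high <= 1))
    stop("cutoff ordering violated: need 0 <= chi_pure_low < chi_pure_high <= 1")
  structure(list(deprot_lambda_min = deprot_lambda_min,
                 prot_lambda_max = prot_lambda_max,
                 chi_pure_low = chi_pure_low,
                 chi_pure_high = chi_pure_high),
            class = "state_cutoffs")
}

#' Classify per-frame protonation states from (lambda, chi)
#'
#' A frame is deprotonated when lambda >= `deprot_lambda_min` and chi is pure
#' (absent, below `chi_pure_low`, or above `chi_pure_high`); protonated when
#' lambda <= `prot_lambda_max` under the same chi purity condition; every
#' other frame — lambda in the open middle band or mixed chi — is discarded.
#' For single-site residues pass `chi = NA`: the purity condition is then
#' vacuously true.
#'
#' @param lambda numeric vector of titration coordinates in \[0, 1\].
#' @param chi numeric vector of tautomer coordinates in \[0, 1\], or `NA`
#'   where absent. Recycled to the length of `lambda` if scalar.
#' @param cutoffs a [state_cutoffs()] object.
#' @param residue_id,frame optional context used in error messages when a
#'   malformed record is rejected.
#' @return factor with levels `deprotonated`, `protonated`, `discarded`.
#' @examples
#' classify_state(c(0.9, 0.1, 0.5), c(0.1, 0.5, 0.9))
#' @export
classify_state <- function(lambda, chi = NA_real_, cutoffs = state_cutoffs(),
                           residue_id = NULL, frame = NULL) {
  stopifnot(inherits(cutoffs, "state_cutoffs"))
  if (length(chi) == 1L) chi <- rep(chi, length(lambda))
  if (length(chi) != length(lambda))
    stop("lambda and chi must have equal length")
  bad <- which(!is.finite(lambda) | lambda < 0 | lambda > 1)
  if (length(bad) > 0L)
    stop(sprintf("lambda outside [0,1]%s%s: first offending value %s at position %d",
                 if (is.null(residue_id)) "" else paste0(" for residue ", residue_id),
                 if (is.null(frame)) "" else paste0(" (frame ", frame[bad[1L]], ")"),
                 format(lambda[bad[1L]]), bad[1L]))
  bad_chi <- which(!is.na(chi) & (chi < 0 | chi > 1))
  if (length(bad_chi) > 0L)
    stop(sprintf("chi outside [0,1]: first offending value %s at position %d",
                 format(chi[bad_chi[1L]]), bad_chi[1L]))
  chi_pure <- is.na(chi) | chi < cutoffs$chi_pure_low | chi > cutoffs$chi_pure_high
  state <- rep("discarded", length(lambda))
  state[lambda >= cutoffs$deprot_lambda_min & chi_pure] <- "deprotonated"
  state[lambda <= cutoffs$prot_lambda_max & chi_pure] <- "protonated"
  factor(state, levels = c("deprotonated", "protonated", "discarded"))
}

#' Tally pure protonation states over one residue's frame series
#'
#' Counts, over all frames of a single residue at one pH, how many frames are
#' pure deprotonated, pure protonated, or discarded (mid-lambda or mixed
#' tautomer). The partition `n_deprot + n_prot + n_discarded = n_total` always
#' holds.
#'
#' @param records data frame with columns `frame`, `residue_id`, `lambda`,
#'   and optionally `chi` (`NA` for single-site residues), all belonging to
#'   one residue.
#' @param cutoffs a [state_cutoffs()] object.
#' @return An object of class `protonation_counts`: a list with
#'   `residue_id`, `n_deprot`, `n_prot`, `n_discarded`, `n_total`.
#' @export
count_states <- function(records, cutoffs = state_cutoffs()) {
  records <- validate_titration_records(records)
  if (nrow(records) == 0L)
    stop("empty record series: no frames to count")
  rid <- unique(records$residue_id)
  if (length(rid) != 1L)
    stop("count_states expects records for exactly one residue, got: ",
         paste(rid, collapse = ", "))
  st <- classify_state(records$lambda, records$chi, cutoffs,
                       residue_id = rid, frame = records$frame)
  tab <- table(st)
  out <- structure(list(residue_id = rid,
                        n_deprot = as.integer(tab[["deprotonated"]]),
                        n_prot = as.integer(tab[["protonated"]]),
                        n_discarded = as.integer(tab[["discarded"]]),
                        n_total = nrow(records)),
                   class = "protonation_counts")
  stopifnot(out$n_deprot + out$n_prot + out$n_discarded == out$n_total)
  out
}

#' @export
print.protonation_counts <- function(x, ...) {
  cat(sprintf("Protonation counts for %s: %d deprotonated, %d protonated, %d discarded (of %d frames)\n",
              x$residue_id, x$n_deprot, x$n_prot, x$n_discarded, x$n_total))
  invisible(x)
}

#' Deprotonated fraction S from pure-state counts
#'
#' S = n_deprot / (n_deprot + n_prot). Discarded frames never enter the
#' denominator. When a pH window yields no pure states at all the fraction is
#' undefined; `NA` is returned with a warning and the point must be excluded
#' from curve fitting.
#'
#' @param counts a `protonation_counts` object from [count_states()], or a
#'   list with fields `n_deprot` and `n_prot`.
#' @return deprotonated fraction in \[0, 1\], or `NA` if no pure states.
#' @export
deprotonated_fraction <- function(counts) {
  nd <- counts$n_deprot; np <- counts$n_prot
  stopifnot(is.numeric(nd), is.numeric(np), nd >= 0, np >= 0)
  if (nd + np == 0) {
    warning("no pure protonation states: deprotonated fraction undefined")
    return(NA_real_)
  }
  nd / (nd + np)
}

#' Running deprotonated fraction along a trajectory
#'
#' Convergence diagnostic: element k is the deprotonated fraction computed
#' over frames 1..k. Prefixes in which no pure state has yet occurred are
#' `NA` (flagged, never interpolated).
#'
#' @inheritParams count_states
#' @return data frame with columns `frame`, `cumulative_fraction`.
#' @export
cumulative_fraction_series <- function(records, cutoffs = state_cutoffs()) {
  records <- validate_titration_records(records)
  if (nrow(records) == 0L) stop("empty record series")
  rid <- unique(records$residue_id)
  if (length(rid) != 1L)
    stop("cumulative_fraction_series expects one residue's series")
  st <- classify_state(records$lambda, records$chi, cutoffs,
                       residue_id = rid, frame = records$frame)
  cum_d <- cumsum(st == "deprotonated")
  cum_p <- cumsum(st == "protonated")
  denom <- cum_d + cum_p
  frac <- ifelse(denom > 0, cum_d / denom, NA_real_)
  data.frame(frame = records$frame, cumulative_fraction = frac)
}

#' Charge set for a titratable residue's atoms
#'
#' Partial charges of the deprotonated (`q_deprot`) and protonated
#' (`q_prot`) end states, in elementary charge units, used for linear
#' interpolation along lambda.
#'
#' @param atom_names character vector of atom names.
#' @param q_prot,q_deprot numeric vectors of end-state charges, same length
#'   as `atom_names`.
#' @return object of class `charge_set`.
#' @export
charge_set <- function(atom_names, q_prot, q_deprot) {
  if (length(atom_names) != length(q_prot) || length(q_prot) != length(q_deprot))
    stop("atom_names, q_prot and q_deprot must have equal length")
  structure(list(atom_names = as.character(atom_names),
                 q_prot = as.numeric(q_prot),
                 q_deprot = as.numeric(q_deprot)),
            class = "charge_set")
}

#' Interpolate per-atom charges along lambda
#'
#' q(lambda) = lambda * q_deprot + (1 - lambda) * q_prot, element-wise, so the
#' endpoints reproduce the end-state charge sets exactly.
#'
#' @param lambda_value scalar lambda in \[0, 1\].
#' @param charges a [charge_set()].
#' @return named numeric vector of interpolated charges.
#' @export
interpolate_charges <- function(lambda_value, charges) {
  stopifnot(inherits(charges, "charge_set"),
            is.numeric(lambda_value), length(lambda_value) == 1L)
  if (!is.finite(lambda_value) || lambda_value < 0 || lambda_value > 1)
    stop("lambda must lie in [0,1]")
  q <- lambda_value * charges$q_deprot + (1 - lambda_value) * charges$q_prot
  names(q) <- charges$atom_names
  q
}

#' Generalized Henderson-Hasselbalch (Hill) titration curve
#'
#' S(pH) = 1 / (1 + 10^(n (pKa - pH))): the deprotonated fraction as a
#' function of pH, with Hill coefficient n. By construction S(pKa) = 0.5 and
#' the curve is strictly increasing in pH for n > 0.
#'
#' @param ph numeric vector of pH values.
#' @param pka acid dissociation constant (pH at the titration midpoint).
#' @param n Hill coefficient (> 0); 1 for an ideal single independent site.
#' @return deprotonated fractions in (0, 1).
#' @examples
#' hh_curve(4, pka = 4, n = 1)  # 0.5 at the midpoint
#' @export
hh_curve <- function(ph, pka, n = 1) {
  1 / (1 + 10^(n * (pka - ph)))
}

#' Build titration points from per-pH record sets
#'
#' Convenience wrapper applying [count_states()] and
#' [deprotonated_fraction()] at every pH for one residue. pH windows with no
#' pure states get `NA` fractions and are dropped by the fitter with a
#' warning.
#'
#' @param records_by_ph named list of record data frames, names are the pH
#'   values (or a list with `ph` attributes as written by
#'   [read_titration_records()]).
#' @param cutoffs a [state_cutoffs()].
#' @return data frame with columns `ph`, `fraction_deprot`, `n_deprot`,
#'   `n_prot`, `n_discarded`, `n_total`.
#' @export
titration_points <- function(records_by_ph, cutoffs = state_cutoffs()) {
  phs <- names(records_by_ph)
  if (is.null(phs)) stop("records_by_ph must be a named list (names = pH values)")
  rows <- lapply(seq_along(records_by_ph), function(i) {
    cnt <- count_states(records_by_ph[[i]], cutoffs)
    frac <- if (cnt$n_deprot + cnt$n_prot > 0)
      cnt$n_deprot / (cnt$n_deprot + cnt$n_prot) else NA_real_
    data.frame(ph = as.numeric(phs[i]), fraction_deprot = frac,
               n_deprot = cnt$n_deprot, n_prot = cnt$n_prot,
               n_discarded = cnt$n_discarded, n_total = cnt$n_total)
  })
  do.call(rbind, rows)
}

#' Fit the generalized Henderson-Hasselbalch curve to titration points
#'
#' Bounded nonlinear least squares of S(pH) = 1/(1 + 10^(n (pKa - pH))) in
#' (pKa, n) with n constrained positive. Initialization: pKa at the pH of
#' the point closest to S = 0.5 (grid midpoint if all points are extreme),
#' n = 1. Points with undefined fractions (no pure states at that pH) are
#' dropped with a warning. When every observed fraction is above 0.95 the
#' midpoint lies below the simulated pH grid and the pKa is only bounded
#' from above (`ph_range_flag = "below_grid"`, `converged = FALSE`);
#' symmetrically `"above_grid"` when all fractions are below 0.05. The fit
#' never extrapolates a point estimate outside the grid in those cases.
#'
#' @param points data frame with columns `ph` and `fraction_deprot`
#'   (e.g. from [titration_points()]); extra count columns are used for
#'   optional weighting.
#' @param residue_id identifier carried into the result.
#' @param weights `NULL` for an unweighted fit (default), or `"counts"` to
#'   weight each pH point by its number of pure-state frames.
#' @return object of class `titration_fit` with fields `residue_id`, `pka`,
#'   `hill_n`, `residual_norm`, `converged`, `ph_range_flag`
#'   (`in_range` / `below_grid` / `above_grid`), and the fitted `points`.
#' @examples
#' pts <- data.frame(ph = 3:7, fraction_deprot = hh_curve(3:7, 4, 1))
#' fit <- fit_titration_curve(pts, "ASP6")
#' c(fit$pka, fit$hill_n)
#' @export
fit_titration_curve <- function(points, residue_id = "residue",
                                weights = NULL) {
  stopifnot(is.data.frame(points),
            all(c("ph", "fraction_deprot") %in% names(points)))
  drop <- !is.finite(points$fraction_deprot)
  if (any(drop)) {
    warning(sprintf("dropping %d pH point(s) with undefined fractions (no pure states): pH %s",
                    sum(drop), paste(points$ph[drop], collapse = ", ")))
    points <- points[!drop, , drop = FALSE]
  }
  if (nrow(points) < 3L)
    stop("need at least 3 pH points with defined fractions to fit 2 parameters")
  if (length(unique(points$ph)) < 2L)
    stop("need at least 2 distinct pH values")
  ph <- points$ph; S <- points$fraction_deprot
  w <- rep(1, length(ph))
  if (identical(weights, "counts")) {
    if (!all(c("n_deprot", "n_prot") %in% names(points)))
      stop("weights = \"counts\" requires n_deprot and n_prot columns")
    w <- points$n_deprot + points$n_prot
    w <- w / mean(w)
  } else if (!is.null(weights)) stop("weights must be NULL or \"counts\"")

  flag <- "in_range"
  if (all(S > 0.95)) flag <- "below_grid"
  if (all(S < 0.05)) flag <- "above_grid"
  if (flag != "in_range") {
    # unidentifiable: report the grid edge as a one-sided bound, no estimate
    pka_bound <- if (flag == "below_grid") min(ph) else max(ph)
    return(structure(list(residue_id = residue_id, pka = pka_bound,
                          hill_n = NA_real_, residual_norm = NA_real_,
                          converged = FALSE, ph_range_flag = flag,
                          points = points),
                     class = "titration_fit"))
  }

  rss <- function(par) sum(w * (hh_curve(ph, par[1L], par[2L]) - S)^2)
  pka0 <- ph[which.min(abs(S - 0.5))]
  if (length(pka0) == 0L) pka0 <- mean(range(ph))
  opt <- stats::optim(c(pka0, 1), rss, method = "L-BFGS-B",
                      lower = c(min(ph) - 20, 1e-3),
                      upper = c(max(ph) + 20, 50),
                      control = list(factr = 1e4, maxit = 500))
  # the optimizer reports a line-search failure when started at (or reaching)
  # an exact optimum; accept the solution if it is numerically stationary
  grad <- vapply(1:2, function(k) {
    h <- 1e-6; e <- c(0, 0); e[k] <- h
    (rss(opt$par + e) - rss(opt$par - e)) / (2 * h)
  }, numeric(1L))
  structure(list(residue_id = residue_id,
                 pka = opt$par[1L], hill_n = opt$par[2L],
                 residual_norm = sqrt(opt$value),
                 converged = opt$convergence == 0L || max(abs(grad)) < 1e-6,
                 ph_range_flag = flag,
                 points = points),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  if (x$ph_range_flag == "in_range") {
    cat(sprintf("Titration fit for %s: pKa = %.3f, Hill n = %.3f (residual norm %.2e, %s)\n",
                x$residue_id, x$pka, x$hill_n, x$residual_norm,
                if (x$converged) "converged" else "NOT converged"))
  } else {
    cat(sprintf("Titration of %s outside pH grid (%s): pKa %s %.1f (bound only)\n",
                x$residue_id, x$ph_range_flag,
                if (x$ph_range_flag == "below_grid") "<" else ">", x$pka))
  }
  invisible(x)
}

#' @export
predict.titration_fit <- function(object, ph, ...) {
  if (!object$converged)
    stop("cannot predict from a non-converged / out-of-range fit")
  hh_curve(ph, object$pka, object$hill_n)
}

#' Reference pKa table of model-pentapeptide values
#'
#' pKa shifts are reported relative to the intrinsic pKa of the residue type
#' in a short unstructured reference peptide. The shipped defaults (Asp 4.0,
#' Glu 4.4, His 6.5) are conventional model-compound values; supply your own
#' table (or a YAML file mapping residue type to pKa) to match the reference
#' set of your CpHMD parameterisation.
#'
#' @param values named numeric vector mapping three-letter residue type to
#'   reference pKa, or a path to a YAML file with such a mapping.
#' @return named numeric vector of class `reference_pka_table`.
#' @export
reference_pka_table <- function(values = c(ASP = 4.0, GLU = 4.4, HIS = 6.5)) {
  if (is.character(values) && length(values) == 1L) {
    values <- unlist(yaml::read_yaml(values))
  }
  if (is.null(names(values)) || any(names(values) == "") || !is.numeric(values))
    stop("reference table must map residue types to numeric pKa values")
  names(values) <- toupper(names(values))
  structure(values, class = c("reference_pka_table", "numeric"))
}

#' pKa shift relative to the model-pentapeptide reference
#'
#' Delta pKa = fitted pKa minus the reference pKa of the residue type, so a
#' residue whose pKa is raised by its environment (e.g. a buried carboxylate)
#' has a positive shift and one stabilised in its deprotonated form (e.g. by
#' a salt bridge) a negative one.
#'
#' @param fit a converged [fit_titration_curve()] result.
#' @param reference a [reference_pka_table()].
#' @return numeric pKa shift.
#' @export
pka_shift <- function(fit, reference = reference_pka_table()) {
  stopifnot(inherits(fit, "titration_fit"))
  if (!isTRUE(fit$converged))
    stop("pKa shift requires a converged fit (", fit$residue_id,
         " flagged ", fit$ph_range_flag, ")")
  type <- residue_type(fit$residue_id)
  if (!type %in% names(reference))
    stop("no reference pKa for residue type '", type,
         "': add it to the reference table")
  unname(fit$pka - reference[[type]])
}

# "ASP6" -> "ASP"; tolerates one-letter+number ids by returning them as-is
residue_type <- function(residue_id) {
  m <- regmatches(residue_id, regexpr("^[A-Za-z]+", residue_id))
  if (length(m) == 0L) return(toupper(residue_id))
  toupper(m)
}

# shared record validation: columns, types, ranges, frame monotonicity
validate_titration_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("frame", "residue_id", "lambda")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (!"chi" %in% names(records)) records$chi <- NA_real_
  if (nrow(records) == 0L) return(records)
  if (any(!is.finite(records$frame) | records$frame < 0))
    stop("frame indices must be non-negative")
  for (rid in unique(records$residue_id)) {
    f <- records$frame[records$residue_id == rid]
    if (is.unsorted(f, strictly = TRUE))
      stop("frame indices must be strictly increasing within residue ", rid)
  }
  records
}
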