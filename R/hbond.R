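# Geometric hydrogen-bond detection, residue-water bond statistics, the
# strict-persistence time autocorrelation and the bi-exponential lifetime
# fit.

#' Geometric hydrogen-bond criterion
#'
#' A hydrogen bond exists when the donor-acceptor distance is at most
#' \code{max_da_dist} and the donor-hydrogen-acceptor angle deviates from
#' linear (180 degrees) by at most \code{max_angle_dev}.
#'
#' @param max_da_dist maximum donor-acceptor distance, Angstrom (default 3.5).
#' @param max_angle_dev maximum deviation from linearity, degrees (default 35).
#' @return Object of class \code{cf_hbond_criterion}.
#' @export
hbond_criterion <- function(max_da_dist = 3.5, max_angle_dev = 35) {
  stopifnot(max_da_dist > 0, max_angle_dev > 0, max_angle_dev <= 180)
  structure(list(max_da_dist = max_da_dist, max_angle_dev = max_angle_dev,
                 min_angle = 180 - max_angle_dev),
            class = "cf_hbond_criterion")
}

#' Load the donor/acceptor atom table
#'
#' Per-residue-type donor (heavy atom + polar hydrogens) and acceptor
#' tables; the shipped defaults cover water, hydronium and the polar side
#' chains in CHARMM naming and can be replaced by any YAML file with the
#' same layout.
#'
#' @param path optional YAML file; default: the package's table.
#' @return Named list keyed by residue type.
#' @export
hbond_atom_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hbond_atoms.yml", package = "channelflow")
  yaml::read_yaml(path)
}

#' Resolve donors and acceptors for a set of residues
#'
#' @param topology a \code{cf_topology}.
#' @param residues data.frame with \code{chain} and \code{resid}, or the
#'   string \code{"water"} (all water residues) or \code{"hydronium"}.
#' @param table donor/acceptor table from \code{\link{hbond_atom_table}}.
#' @return List with \code{donors} (data.frame \code{donor},
#'   \code{hydrogen} atom indices), \code{acceptors} (atom indices) and
#'   \code{atoms} (all atom indices involved).
#' @export
resolve_hbond_group <- function(topology, residues,
                                table = hbond_atom_table()) {
  if (is.character(residues) && length(residues) == 1) {
    resn <- switch(residues,
                   water = c("TIP3", "HOH", "WAT", "SOL"),
                   hydronium = "H3O",
                   stop("unknown residue group: ", residues))
    idx <- select_atoms(topology, resname = resn)
    rows <- unique(topology[idx, c("chain", "resid")])
  } else rows <- residues
  don_d <- integer(0); don_h <- integer(0); acc <- integer(0)
  for (i in seq_len(nrow(rows))) {
    sel <- select_atoms(topology, chain = rows$chain[i],
                        resid = rows$resid[i])
    if (length(sel) == 0) next
    for (rt in unique(topology$resname[sel])) {
      entry <- table[[rt]]
      if (is.null(entry)) next
      rsel <- sel[topology$resname[sel] == rt]
      nm <- topology$name[rsel]
      for (dn in entry$donors) {
        d <- rsel[nm == dn$d]
        if (length(d) != 1) next
        for (hn in dn$h) {
          h <- rsel[nm == hn]
          if (length(h) == 1) { don_d <- c(don_d, d); don_h <- c(don_h, h) }
        }
      }
      for (an in entry$acceptors) acc <- c(acc, rsel[nm == an])
    }
  }
  list(donors = data.frame(donor = don_d, hydrogen = don_h),
       acceptors = unique(acc),
       atoms = unique(c(don_d, don_h, acc)))
}

#' Detect hydrogen bonds in one frame
#'
#' Applies the geometric criterion to every donor-hydrogen/acceptor
#' combination.  Bonds within the same residue are excluded.
#'
#' @param coords \code{n_atoms x 3} coordinate matrix of the frame.
#' @param topology a \code{cf_topology} (for residue bookkeeping).
#' @param donors data.frame with atom-index columns \code{donor} and
#'   \code{hydrogen} (hydrogen covalently bound to the donor).
#' @param acceptors integer vector of acceptor atom indices.
#' @param criterion a \code{\link{hbond_criterion}}.
#' @return data.frame of events: \code{donor}, \code{hydrogen},
#'   \code{acceptor} atom indices plus donor/acceptor residue keys.
#' @export
detect_hbonds <- function(coords, topology, donors, acceptors,
                          criterion = hbond_criterion()) {
  if (nrow(donors) == 0 || length(acceptors) == 0)
    return(empty_events())
  D <- coords[donors$donor, , drop = FALSE]
  H <- coords[donors$hydrogen, , drop = FALSE]
  A <- coords[acceptors, , drop = FALSE]
  nd <- nrow(D); na_ <- nrow(A)
  # donor-acceptor distances (nd x na)
  d2 <- outer(rowSums(D^2), rep(1, na_)) + outer(rep(1, nd), rowSums(A^2)) -
    2 * (D %*% t(A))
  d2[d2 < 0] <- 0
  ok <- sqrt(d2) <= criterion$max_da_dist
  # same-residue exclusion and self-pairs
  dres <- paste0(topology$chain[donors$donor], ":",
                 topology$resid[donors$donor])
  ares <- paste0(topology$chain[acceptors], ":", topology$resid[acceptors])
  ok <- ok & outer(dres, ares, `!=`)
  hit <- which(ok, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_events())
  hd <- D[hit[, 1], , drop = FALSE] - H[hit[, 1], , drop = FALSE]
  ha <- A[hit[, 2], , drop = FALSE] - H[hit[, 1], , drop = FALSE]
  cosang <- rowSums(hd * ha) /
    (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  keep <- ang >= criterion$min_angle
  hit <- hit[keep, , drop = FALSE]
  if (nrow(hit) == 0) return(empty_events())
  data.frame(donor = donors$donor[hit[, 1]],
             hydrogen = donors$hydrogen[hit[, 1]],
             acceptor = acceptors[hit[, 2]],
             donor_res = dres[hit[, 1]],
             acceptor_res = ares[hit[, 2]],
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(donor = integer(0), hydrogen = integer(0),
             acceptor = integer(0), donor_res = character(0),
             acceptor_res = character(0), stringsAsFactors = FALSE)
}

#' Per-frame hydrogen-bond counts between two groups
#'
#' Counts bonds in both donation directions (group A donating to B and B
#' donating to A) in every frame.
#'
#' @param traj a \code{cf_trajectory}.
#' @param group_a,group_b residue specifications as accepted by
#'   \code{\link{resolve_hbond_group}}.
#' @param criterion a \code{\link{hbond_criterion}}.
#' @param table donor/acceptor table.
#' @return Object of class \code{cf_hbond_series}: integer \code{counts}
#'   per frame, binary \code{h} (\code{counts >= 1}), \code{dt} (ps),
#'   mean count and bond probability.
#' @export
hbond_count_series <- function(traj, group_a, group_b,
                               criterion = hbond_criterion(),
                               table = hbond_atom_table()) {
  ga <- resolve_hbond_group(traj$topology, group_a, table)
  gb <- resolve_hbond_group(traj$topology, group_b, table)
  if (nrow(ga$donors) == 0 && nrow(gb$donors) == 0)
    stop("configuration error: neither group has any donor hydrogens")
  nf <- n_frames(traj)
  counts <- integer(nf)
  for (i in seq_len(nf)) {
    fc <- frame_coords(traj, i)
    e1 <- detect_hbonds(fc, traj$topology, ga$donors, gb$acceptors, criterion)
    e2 <- detect_hbonds(fc, traj$topology, gb$donors, ga$acceptors, criterion)
    counts[i] <- nrow(e1) + nrow(e2)
  }
  structure(list(counts = counts, h = as.integer(counts >= 1),
                 dt = traj$frame_interval,
                 mean_count = mean(counts), probability = mean(counts >= 1)),
            class = "cf_hbond_series")
}

#' Residue-water hydrogen-bond statistics
#'
#' Mean number (and probability) of hydrogen bonds between one residue and
#' any water molecule, per frame, in either donation direction.
#'
#' @param traj a \code{cf_trajectory}.
#' @param residue data.frame row with \code{chain} and \code{resid}.
#' @param criterion a \code{\link{hbond_criterion}}.
#' @param table donor/acceptor table.
#' @param partner \code{"water"} (default) or \code{"hydronium"} or another
#'   residue specification.
#' @return A \code{cf_hbond_series}.
#' @export
residue_water_hbond_stats <- function(traj, residue,
                                      criterion = hbond_criterion(),
                                      table = hbond_atom_table(),
                                      partner = "water") {
  hbond_count_series(traj, residue, partner, criterion, table)
}

#' Strict-persistence hydrogen-bond autocorrelation
#'
#' For time origins spaced \code{origin_spacing} ps apart (non-overlapping
#' by default), \code{C(tau)} is the fraction of bonded origins whose bond
#' persists through every saved frame of \code{[t0, t0 + tau]} (the
#' partner water and the atoms involved may change; any frame without a
#' bond breaks persistence).  The ratio-of-sums form is used: numerator
#' \code{sum_t0 h(t0) persist(t0, tau)}, denominator \code{sum_t0 h(t0)^2}.
#'
#' @param series a \code{cf_hbond_series}, or a binary vector (then
#'   \code{dt} must be given).
#' @param max_lag maximal lag time, ps (default 100).
#' @param origin_spacing spacing between time origins, ps (default 120).
#' @param dt frame interval in ps (taken from \code{series} when absent).
#' @return Object of class \code{cf_autocorr}: \code{tau} (ps), \code{C},
#'   \code{n_origins}, \code{n_bonded_origins}.
#' @export
hbond_autocorrelation <- function(series, max_lag = 100,
                                  origin_spacing = 120, dt = NULL) {
  if (inherits(series, "cf_hbond_series")) {
    h <- series$h
    if (is.null(dt)) dt <- series$dt
  } else h <- as.integer(series != 0)
  if (is.null(dt)) stop("dt must be supplied for a bare series")
  nlag <- floor(max_lag / dt)
  nfr <- length(h)
  if (nfr <= nlag) stop("series shorter than the maximal lag")
  spacing <- max(1L, as.integer(round(origin_spacing / dt)))
  origins <- seq(1L, nfr - nlag, by = spacing)
  # streak[i]: number of consecutive frames with h==1 starting at i
  streak <- integer(nfr)
  run <- 0L
  for (i in nfr:1) {
    run <- if (h[i] == 1L) run + 1L else 0L
    streak[i] <- run
  }
  s0 <- streak[origins]
  denom <- sum(s0 >= 1L)
  if (denom == 0)
    stop("undefined correlation: no bonded time origin")
  ks <- 0:nlag
  C <- vapply(ks, function(k) sum(s0 >= k + 1L), numeric(1)) / denom
  structure(list(tau = ks * dt, C = C, n_origins = length(origins),
                 n_bonded_origins = denom, dt = dt),
            class = "cf_autocorr")
}

#' Average autocorrelation curves over replicas
#'
#' @param curves list of \code{cf_autocorr} on identical lag grids.
#' @return A \code{cf_autocorr} with the bonded-origin-weighted mean curve.
#' @export
average_autocorr <- function(curves) {
  w <- vapply(curves, function(cv) cv$n_bonded_origins, numeric(1))
  Cm <- Reduce(`+`, Map(function(cv, wi) cv$C * wi, curves, w)) / sum(w)
  structure(list(tau = curves[[1]]$tau, C = Cm,
                 n_origins = sum(vapply(curves, function(cv) cv$n_origins,
                                        numeric(1))),
                 n_bonded_origins = sum(w), dt = curves[[1]]$dt),
            class = "cf_autocorr")
}

#' Bi-exponential hydrogen-bond lifetime fit
#'
#' Fits \code{C(t) = A exp(-t/tau1) + B exp(-t/tau2)} with \code{A + B = 1},
#' \code{A, B} in \code{[0, 1]} and positive time constants, by constrained
#' nonlinear least squares (uniform weights over the lag grid, multistart on
#' non-convergence).  The reported lifetime is the weighted sum
#' \code{tau = A tau1 + B tau2}.  Fits are flagged "not determined" on
#' non-convergence, when the slow constant exceeds five times the maximal
#' lag, or when a parameter's standard error exceeds the parameter.
#'
#' @param curve a \code{cf_autocorr} (or list with \code{tau}, \code{C}).
#' @return Object of class \code{cf_lifetime}: \code{A}, \code{B},
#'   \code{tau1}, \code{tau2} (tau1 <= tau2), weighted \code{tau},
#'   \code{residual} (RMS), \code{determined} flag and \code{reason}.
#' @export
fit_lifetime <- function(curve) {
  tau <- curve$tau
  C <- curve$C
  ok <- is.finite(C)
  tau <- tau[ok]; C <- C[ok]
  if (length(tau) < 5) stop("need at least 5 lag points with defined C")
  max_lag <- max(tau)
  # constraints enforced by reparameterisation: A = logistic(a),
  # tau_i = tau_cap * logistic(l_i).  The cap (five times the maximal lag)
  # removes the noise-floor degeneracy where a vanishing amplitude on an
  # arbitrarily slow component absorbs the baseline; a fit pushed onto the
  # cap is flagged as not determined.
  tau_cap <- 5 * max_lag
  model <- function(par) {
    A <- stats::plogis(par[1])
    t1 <- tau_cap * stats::plogis(par[2])
    t2 <- tau_cap * stats::plogis(par[3])
    A * exp(-tau / t1) + (1 - A) * exp(-tau / t2)
  }
  qtau <- function(x) stats::qlogis(min(x, 0.98 * tau_cap) / tau_cap)
  starts <- list(c(0, qtau(5), qtau(50)),
                 c(stats::qlogis(0.8), qtau(2), qtau(20)),
                 c(stats::qlogis(0.3), qtau(10), qtau(100)),
                 c(0, qtau(1), qtau(200)),
                 c(stats::qlogis(0.9), qtau(20), qtau(80)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = function(p) C - model(p),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance < 1e-20) break
  }
  if (is.null(best))
    return(structure(list(A = NA_real_, B = NA_real_, tau1 = NA_real_,
                          tau2 = NA_real_, tau = NA_real_,
                          residual = NA_real_, determined = FALSE,
                          reason = "fit did not converge"),
                     class = "cf_lifetime"))
  p <- best$par
  A <- stats::plogis(p[1])
  t1 <- tau_cap * stats::plogis(p[2])
  t2 <- tau_cap * stats::plogis(p[3])
  se_t <- tryCatch(sqrt(diag(best$deviance / max(length(tau) - 3, 1) *
                               solve(best$hessian))),
                   error = function(e) rep(NA_real_, 3))
  # delta method back to the natural scale
  se <- c(A = se_t[1] * A * (1 - A),
          t1 = se_t[2] * t1 * (1 - t1 / tau_cap),
          t2 = se_t[3] * t2 * (1 - t2 / tau_cap))
  if (t1 > t2) {
    tmp <- t1; t1 <- t2; t2 <- tmp
    A <- 1 - A
    se <- se[c(1, 3, 2)]
  }
  B <- 1 - A
  wtau <- A * t1 + B * t2
  reason <- NULL
  if (t2 > 0.99 * tau_cap)
    reason <- "slow time constant beyond resolvable range"
  big_se <- !is.na(se) & se > c(max(A, 1e-8), t1, t2)
  if (is.null(reason) && any(big_se))
    reason <- "parameter uncertainty exceeds parameter"
  structure(list(A = A, B = B, tau1 = t1, tau2 = t2, tau = wtau,
                 residual = sqrt(best$deviance / length(tau)),
                 determined = is.null(reason),
                 reason = if (is.null(reason)) NA_character_ else reason),
            class = "cf_lifetime")
}

#' @export
print.cf_lifetime <- function(x, ...) {
  if (x$determined)
    cat(sprintf(
      "H-bond lifetime: tau = %.2f ps (A=%.2f tau1=%.2f, B=%.2f tau2=%.2f)\n",
      x$tau, x$A, x$tau1, x$B, x$tau2))
  else cat("H-bond lifetime not determined:", x$reason, "\n")
  invisible(x)
}
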