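#' Directionality index of each bin
#'
#' For each bin, sums balanced contacts to bins within `window` upstream (A)
#' and downstream (B), truncated at chromosome ends, and scores the bias as
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)` with
#' `E = (A + B) / 2`. DI is 0 when `A == B` and undefined when `A + B == 0`.
#'
#' @param m A balanced `contact_matrix`.
#' @param window One-sided window in bp (default 2 Mb).
#' @return A `scalar_track` of DI values with a `window` attribute.
#' @export
directionality_index <- function(m, window = 2e6) {
  if (m$kind != "balanced") stopf("directionality_index expects a balanced matrix")
  bins <- m$bins
  bs <- bin_size_of(bins)
  w <- round(window / bs)
  if (w < 2) stopf("window must span at least 2 bins")
  di <- rep(NA_real_, nrow(bins))
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    k <- length(rows)
    sub <- m$mat[rows, rows, drop = FALSE]
    for (i in seq_len(k)) {
      if (m$mask[rows[i]]) next
      up <- max(1, i - w):(i - 1)
      dn <- (i + 1):min(k, i + w)
      A <- if (i == 1) 0 else sum(sub[i, up], na.rm = TRUE)
      B <- if (i == k) 0 else sum(sub[i, dn], na.rm = TRUE)
      if (A + B == 0) next
      E <- (A + B) / 2
      di[rows[i]] <- if (A == B) 0 else sign(B - A) * ((A - E)^2 + (B - E)^2) / E
    }
  }
  out <- scalar_track(bins, di)
  attr(out, "window") <- window
  out
}

# --- 3-state Gaussian HMM (down-bias / none / up-bias), EM + Viterbi -------

hmm_init <- function(x) {
  s <- stats::sd(x)
  if (s == 0) s <- 1
  list(mu = c(-s, 0, s), sigma = rep(max(s, 1e-8), 3),
       pi = rep(1 / 3, 3),
       A = matrix(c(0.9, 0.05, 0.05,
                    0.05, 0.9, 0.05,
                    0.05, 0.05, 0.9), 3, 3, byrow = TRUE))
}

hmm_em <- function(x, par, max_iter = 100, tol = 1e-6) {
  n <- length(x); K <- 3
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(1:K, function(k)
      stats::dnorm(x, par$mu[k], par$sigma[k]), numeric(n))
    dens <- pmax(dens, 1e-300)
    # scaled forward-backward
    alpha <- matrix(0, n, K); beta <- matrix(0, n, K); cvec <- numeric(n)
    a <- par$pi * dens[1, ]
    cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% par$A) * dens[t, ]
      cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
    }
    beta[n, ] <- 1
    for (t in (n - 1):1)
      beta[t, ] <- (par$A %*% (dens[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    ll <- sum(log(cvec))
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    xi <- matrix(0, K, K)
    for (t in 1:(n - 1)) {
      m <- outer(alpha[t, ], dens[t + 1, ] * beta[t + 1, ]) * par$A
      xi <- xi + m / sum(m)
    }
    par$pi <- gamma[1, ]
    par$A <- xi / rowSums(xi)
    Nk <- colSums(gamma)
    par$mu <- colSums(gamma * x) / Nk
    par$sigma <- sqrt(pmax(colSums(gamma * (outer(x, par$mu, `-`))^2) / Nk,
                           1e-10))
    if (!is.finite(ll)) return(NULL)
    if (ll < ll_old - 1e-6) return(NULL)  # EM must not decrease
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  par
}

hmm_viterbi <- function(x, par) {
  n <- length(x); K <- 3
  logd <- vapply(1:K, function(k)
    stats::dnorm(x, par$mu[k], par$sigma[k], log = TRUE), numeric(n))
  logA <- log(pmax(par$A, 1e-300))
  V <- matrix(-Inf, n, K); ptr <- matrix(0L, n, K)
  V[1, ] <- log(pmax(par$pi, 1e-300)) + logd[1, ]
  for (t in 2:n) for (k in 1:K) {
    cand <- V[t - 1, ] + logA[, k]
    ptr[t, k] <- which.max(cand)
    V[t, k] <- cand[ptr[t, k]] + logd[t, k]
  }
  path <- integer(n)
  path[n] <- which.max(V[n, ])
  for (t in (n - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
  path
}

# fallback segmentation when EM degenerates: threshold at +/- 0.5 sd
hmm_threshold_states <- function(x) {
  s <- stats::sd(x); if (s == 0) s <- 1
  ifelse(x > 0.5 * s, 3L, ifelse(x < -0.5 * s, 1L, 2L))
}

# domain grammar: a domain runs from the start of a maximal downstream-bias
# (positive, state 3) run to the end of the last upstream-bias (negative,
# state 1) run encountered before the next downstream-bias run; intervening
# no-bias runs are absorbed
states_to_domains <- function(states) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  domains <- list()
  i <- 1
  while (i <= length(r$values)) {
    if (r$values[i] == 3L) {
      j <- i + 1
      last_n <- NA
      while (j <= length(r$values) && r$values[j] != 3L) {
        if (r$values[j] == 1L) last_n <- j
        j <- j + 1
      }
      if (!is.na(last_n)) {
        domains[[length(domains) + 1L]] <- c(starts[i], ends[last_n])
        i <- j
        next
      }
    }
    i <- i + 1
  }
  domains
}

#' Call TADs from a DI track with a 3-state Gaussian HMM
#'
#' Fits a hidden Markov model with downstream-bias, no-bias and upstream-bias
#' states (Gaussian emissions, deterministic moment-based initialisation) to
#' each chromosome's DI sequence by EM, decodes the Viterbi path, and applies
#' the standard domain grammar: a domain runs from the start of a maximal
#' downstream-bias run to the end of the next upstream-bias run. Inter-domain
#' gaps shorter than `boundary_max` are reported as boundaries.
#'
#' If EM degenerates (likelihood failure), the chromosome falls back to
#' threshold segmentation at half a standard deviation, with a warning.
#'
#' @param di A [directionality_index()] track.
#' @param max_em_iter Maximum EM iterations.
#' @param boundary_max Maximum gap length (bp) still considered a boundary.
#' @param min_domain Minimum domain length in bp; shorter state-run spans
#'   (directionality flickers inside boundary regions) are discarded before
#'   boundaries are derived.
#' @return A list of class `tad_set` with `domains` and `boundaries`
#'   (data frames `chrom`, `start`, `end`).
#' @export
hmm_call_tads <- function(di, max_em_iter = 100, boundary_max = 4e5,
                          min_domain = 2e5) {
  bins <- di
  bs <- bin_size_of(di)
  domains <- list(); boundaries <- list()
  for (cn in unique(bins$chrom)) {
    rows <- which(bins$chrom == cn)
    x <- di$value[rows]
    if (sum(is.finite(x)) < 20) next
    x[!is.finite(x)] <- 0
    # the DI is chi-square-scaled and extremely heavy-tailed; a signed log
    # compression of the magnitude makes Gaussian emissions appropriate
    x <- sign(x) * log1p(abs(x))
    par <- hmm_em(x, hmm_init(x), max_iter = max_em_iter)
    if (is.null(par)) {
      warnf("EM failed on %s; falling back to threshold segmentation", cn)
      states <- hmm_threshold_states(x)
    } else {
      # order states by emission mean: 1 = upstream-bias, 3 = downstream-bias
      ord <- order(par$mu)
      par$mu <- par$mu[ord]; par$sigma <- par$sigma[ord]
      par$pi <- par$pi[ord]; par$A <- par$A[ord, ord]
      states <- hmm_viterbi(x, par)
    }
    doms <- states_to_domains(states)
    doms <- Filter(function(d)
      bins$end[rows[d[2]]] - bins$start[rows[d[1]]] >= min_domain, doms)
    for (d in doms)
      domains[[length(domains) + 1L]] <-
        data.frame(chrom = cn, start = bins$start[rows[d[1]]],
                   end = bins$end[rows[d[2]]], stringsAsFactors = FALSE)
    if (length(doms) > 1) {
      for (k in seq_len(length(doms) - 1)) {
        gs <- bins$end[rows[doms[[k]][2]]]
        ge <- bins$start[rows[doms[[k + 1]][1]]]
        if (ge - gs < boundary_max)
          boundaries[[length(boundaries) + 1L]] <-
            data.frame(chrom = cn, start = gs, end = ge,
                       stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  structure(list(domains = if (length(domains)) do.call(rbind, domains) else empty,
                 boundaries = if (length(boundaries)) do.call(rbind, boundaries) else empty),
            class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf("<tad_set> %d domains, %d boundaries on %d chromosome(s)\n",
              nrow(x$domains), nrow(x$boundaries),
              length(unique(x$domains$chrom))))
  invisible(x)
}

#' Insulation score along the diagonal
#'
#' For each bin `b` far enough from the chromosome ends, averages balanced
#' contacts over the square window spanning `(b - w, b] x (b, b + w]` bins,
#' then expresses each value as log2 over the chromosome mean, and keeps a
#' loess-smoothed copy alongside.
#'
#' @param m A balanced `contact_matrix`.
#' @param window Window size in bp (default 400 kb).
#' @param loess_frac Loess span for the smoothed track.
#' @return A `data.frame` of class `insulation_track` with per-bin `raw`,
#'   `log2` and `smoothed` columns (`NA` outside the defined range).
#' @export
insulation_score <- function(m, window = 4e5, loess_frac = 0.1) {
  if (m$kind != "balanced") stopf("insulation_score expects a balanced matrix")
  bins <- m$bins
  bs <- bin_size_of(bins)
  w <- round(window / bs)
  if (w < 1) stopf("window smaller than one bin")
  n <- nrow(bins)
  raw <- rep(NA_real_, n); l2 <- rep(NA_real_, n); sm <- rep(NA_real_, n)
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    k <- length(rows)
    if (k < 2 * w + 1) { warnf("chromosome %s shorter than twice the window; skipped", cn); next }
    sub <- m$mat[rows, rows, drop = FALSE]
    vals <- rep(NA_real_, k)
    for (b in w:(k - w))
      vals[b] <- mean(sub[(b - w + 1):b, (b + 1):(b + w)], na.rm = TRUE)
    mu <- mean(vals, na.rm = TRUE)
    if (!is.finite(mu) || mu <= 0) next
    l2c <- log2(vals / mu)
    def <- which(is.finite(l2c))
    smc <- rep(NA_real_, k)
    if (length(def) > 10) {
      fit <- stats::loess(l2c[def] ~ def, span = loess_frac,
                          degree = 2, family = "gaussian")
      smc[def] <- stats::predict(fit)
    } else smc <- l2c
    raw[rows] <- vals; l2[rows] <- l2c; sm[rows] <- smc
  }
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    bin_id = bins$bin_id, raw = raw, log2 = l2, smoothed = sm,
                    stringsAsFactors = FALSE)
  attr(out, "bin_size") <- bs
  attr(out, "window") <- window
  class(out) <- c("insulation_track", "data.frame")
  out
}

#' Local minima of the insulation track
#'
#' Candidate TAD boundaries: bins whose insulation (log2 track, lightly
#' smoothed with a 3-bin running mean to suppress single-bin noise) is
#' strictly below both neighbours. The broad loess column is kept for
#' visualisation; boundary detection needs resolution at the TAD scale.
#'
#' @param track An [insulation_score()] result.
#' @return Data frame `chrom`, `start`, `end`, `bin_id` of the minima.
#' @export
insulation_minima <- function(track) {
  out <- list()
  for (cn in unique(track$chrom)) {
    rows <- which(track$chrom == cn)
    s <- track$log2[rows]
    def <- which(is.finite(s))
    if (length(def) >= 3) {
      i <- def[c(-1, -length(def))]
      s[i] <- (track$log2[rows][i - 1] + track$log2[rows][i] +
                 track$log2[rows][i + 1]) / 3
    }
    for (i in seq_along(s)) {
      if (i == 1 || i == length(s)) next
      if (is.finite(s[i]) && is.finite(s[i - 1]) && is.finite(s[i + 1]) &&
          s[i] < s[i - 1] && s[i] < s[i + 1])
        out[[length(out) + 1L]] <-
          data.frame(chrom = cn, start = track$start[rows[i]],
                     end = track$end[rows[i]], bin_id = track$bin_id[rows[i]],
                     stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  bin_id = integer(), stringsAsFactors = FALSE)
}

#' Aggregate insulation profile over rescaled TADs
#'
#' Rescales each domain to unit length, extends by `flank_frac` of its length
#' on each side, interpolates the smoothed insulation onto `n_points` shared
#' coordinates and averages across domains. Domains whose flanked span leaves
#' the defined track are skipped.
#'
#' @param is_track An [insulation_score()] result.
#' @param tads A `tad_set` (or a data frame of domains).
#' @param flank_frac Flank size as a fraction of domain length.
#' @param n_points Number of profile points.
#' @return Data frame `position` (normalised; 0 and 1 are the domain edges)
#'   and `value`, with the number of contributing domains as attribute `n`.
#' @export
tad_profile <- function(is_track, tads, flank_frac = 0.5, n_points = 100) {
  doms <- if (inherits(tads, "tad_set")) tads$domains else tads
  coords <- seq(-flank_frac, 1 + flank_frac, length.out = n_points)
  acc <- numeric(n_points); nused <- 0L
  for (r in seq_len(nrow(doms))) {
    rows <- which(is_track$chrom == doms$chrom[r])
    if (!length(rows)) next
    mid <- (is_track$start[rows] + is_track$end[rows]) / 2
    val <- is_track$smoothed[rows]
    ok <- is.finite(val)
    if (sum(ok) < 4) next
    len <- doms$end[r] - doms$start[r]
    xout <- doms$start[r] + coords * len
    if (min(xout) < min(mid[ok]) || max(xout) > max(mid[ok])) next
    y <- stats::approx(mid[ok], val[ok], xout = xout)$y
    if (anyNA(y)) next
    acc <- acc + y; nused <- nused + 1L
  }
  if (nused == 0) stopf("no domain is fully covered by the insulation track")
  out <- data.frame(position = coords, value = acc / nused)
  attr(out, "n") <- nused
  out
}

#' Classify TAD compartment transitions between two stages
#'
#' Labels each domain by the sign of its mean PC1 in each stage and records
#' the transition (A->A, A->B, B->A, B->B; domains with fully masked PC1 are
#' unclassified).
#'
#' @param tads A `tad_set` or data frame of domains.
#' @param pc1_a,pc1_b `scalar_track`s of PC1 values at compartment resolution.
#' @return A list with per-domain `transitions` data frame and
#'   `percent_switched` over the classified domains.
#' @export
tad_switch_class <- function(tads, pc1_a, pc1_b) {
  doms <- if (inherits(tads, "tad_set")) tads$domains else tads
  lab_of <- function(track, chrom, start, end) {
    rows <- which(track$chrom == chrom & track$end > start & track$start < end)
    v <- track$value[rows]
    if (!length(rows) || all(is.na(v))) return(NA_character_)
    if (mean(v, na.rm = TRUE) > 0) "A" else "B"
  }
  la <- character(nrow(doms)); lb <- character(nrow(doms))
  for (r in seq_len(nrow(doms))) {
    la[r] <- lab_of(pc1_a, doms$chrom[r], doms$start[r], doms$end[r])
    lb[r] <- lab_of(pc1_b, doms$chrom[r], doms$start[r], doms$end[r])
  }
  trans <- ifelse(is.na(la) | is.na(lb), "unclassified", paste0(la, "->", lb))
  classified <- trans != "unclassified"
  switched <- trans %in% c("A->B", "B->A")
  list(transitions = cbind(doms, data.frame(class_a = la, class_b = lb,
                                            transition = trans,
                                            stringsAsFactors = FALSE)),
       percent_switched = if (any(classified))
         100 * sum(switched) / sum(classified) else NA_real_)
}
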