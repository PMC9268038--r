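# Time-independent Franck-Condon engine.
#
# Multidimensional harmonic-oscillator overlaps <v|v'> under a Duschinsky
# map Q' = J(Q - K) are generated from the Gaussian generating function
#
#   G(s,t) = sum_{v,v'} s^v t^{v'} / sqrt(v! v'!) <v|v'>
#          = T00 exp(1/2 s'As + s'Bt + 1/2 t'Ct + a's + b't)
#
# whose matrices follow from a single 3N-dimensional Gaussian integral:
#   C0 = G + J'G'J          (G = diag(omega), G' = diag(omega'), a.u.)
#   A  = 2 L C0^-1 L - I            L  = diag(sqrt(omega))
#   B  = 2 L C0^-1 J' L'            L' = diag(sqrt(omega'))
#   Ct = 2 L' J C0^-1 J' L' - I
#   a  =  sqrt(2) L  C0^-1 U K      U  = J'G'J
#   b  = -sqrt(2) L' J C0^-1 G K
#   T00 = 2^(n/2) det(GG')^(1/4) det(C0)^(-1/2)
#         * exp(-1/2 K'UK + 1/2 K'U C0^-1 U K)
# Differentiating G in s or t yields closed two-term recursions that raise
# one quantum at a time while only referencing equal-or-lower states.

fc_engine <- function(map) {
  n <- map$nmodes
  w <- cm1_to_au(map$freqs_initial)
  wp <- cm1_to_au(map$freqs_final)
  if (any(wp <= 0)) stop("FC engine requires positive final frequencies")
  if (any(w <= 0)) stop("FC engine requires positive initial frequencies")
  J <- map$J
  K <- map$K
  L <- sqrt(w); Lp <- sqrt(wp)
  U <- t(J) %*% (wp * J)            # J' G' J
  C0 <- diag(w, n) + U
  Ci <- solve(C0)
  A <- 2 * (L * Ci) %*% diag(L, n) - diag(n); A <- (A + t(A)) / 2
  B <- 2 * (L * (Ci %*% t(J))) %*% diag(Lp, n)
  Ct <- 2 * (Lp * (J %*% Ci %*% t(J))) %*% diag(Lp, n) - diag(n)
  Ct <- (Ct + t(Ct)) / 2
  a <- sqrt(2) * L * as.numeric(Ci %*% (U %*% K))
  b <- -sqrt(2) * Lp * as.numeric(J %*% (Ci %*% (w * K)))
  ldet <- determinant(C0, logarithm = TRUE)
  T00 <- 2^(n / 2) * exp(0.25 * sum(log(w) + log(wp)) -
                           0.5 * as.numeric(ldet$modulus)) *
    exp(-0.5 * sum(K * (U %*% K)) +
          0.5 * sum((U %*% K) * (Ci %*% (U %*% K))))
  memo <- new.env(parent = emptyenv(), size = 4096L)
  assign(paste(rep(0L, 2 * n), collapse = ","), T00, envir = memo)
  list(n = n, A = A, B = B, Ct = Ct, a = a, b = b, T00 = T00, memo = memo)
}

fc_get <- function(eng, v, vp) {
  key <- paste(c(v, vp), collapse = ",")
  hit <- get0(key, envir = eng$memo, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  n <- eng$n
  if (sum(vp) > 0) {
    k <- which(vp > 0)[1]
    vpl <- vp; vpl[k] <- vpl[k] - 1L
    val <- eng$b[k] * fc_get(eng, v, vpl)
    for (l in seq_len(n)) {
      if (vpl[l] > 0) {
        vv <- vpl; vv[l] <- vv[l] - 1L
        val <- val + eng$Ct[k, l] * sqrt(vpl[l]) * fc_get(eng, v, vv)
      }
    }
    for (i in seq_len(n)) {
      if (v[i] > 0) {
        vi <- v; vi[i] <- vi[i] - 1L
        val <- val + eng$B[i, k] * sqrt(v[i]) * fc_get(eng, vi, vpl)
      }
    }
    val <- val / sqrt(vp[k])
  } else {
    i <- which(v > 0)[1]
    vl <- v; vl[i] <- vl[i] - 1L
    val <- eng$a[i] * fc_get(eng, vl, vp)
    for (j in seq_len(n)) {
      if (vl[j] > 0) {
        vj <- vl; vj[j] <- vj[j] - 1L
        val <- val + eng$A[i, j] * sqrt(vl[j]) * fc_get(eng, vj, vp)
      }
    }
    val <- val / sqrt(v[i])
  }
  if (!is.finite(val)) {
    stop("FC recursion lost stability (quanta too high); truncate earlier")
  }
  assign(key, val, envir = eng$memo)
  val
}

#' Franck-Condon overlap amplitude
#'
#' Exact harmonic-oscillator overlap `<v|v'>` between an initial-state level
#' `v_init` and a final-state level `v_final` under a Duschinsky map,
#' computed by a stable generating-function recursion. The squared amplitude
#' is the Franck-Condon factor.
#'
#' @param map a `DuschinskyMap` with positive final frequencies.
#' @param v_init,v_final nonnegative integer quanta vectors (length nmodes).
#' @return signed real overlap amplitude.
#' @export
fc_overlap <- function(map, v_init, v_final) {
  stopifnot(inherits(map, "DuschinskyMap"))
  v <- as.integer(round(v_init)); vp <- as.integer(round(v_final))
  if (length(v) != map$nmodes || length(vp) != map$nmodes) {
    stop("quanta vectors must have length nmodes")
  }
  if (any(v < 0) || any(vp < 0)) stop("quanta must be nonnegative integers")
  eng <- fc_engine(map)
  fc_get(eng, v, vp)
}

# One-mode submap (used for the factorized J = I fast path).
submap_1d <- function(map, i) {
  new_duschinsky_map(map$model, matrix(1, 1, 1), map$K[i],
                     map$freqs_initial[i], map$freqs_final[i], 0)
}

# Table of 1D overlaps T[v+1, v'+1] = <v|v'> for one mode of a diagonal map.
fc_table_1d <- function(map, i, max_v, max_vp) {
  eng <- fc_engine(submap_1d(map, i))
  tab <- matrix(0, max_v + 1, max_vp + 1)
  for (v in 0:max_v) for (vp in 0:max_vp) {
    tab[v + 1, vp + 1] <- fc_get(eng, v, vp)
  }
  tab
}

stick_spectrum <- function(energies, intensities, init_quanta, final_quanta,
                           meta = list()) {
  ord <- order(energies)
  structure(list(
    energies = energies[ord], intensities = intensities[ord],
    init_quanta = init_quanta[ord, , drop = FALSE],
    final_quanta = final_quanta[ord, , drop = FALSE],
    total_intensity = sum(intensities), meta = meta
  ), class = "StickSpectrum")
}

#' @export
print.StickSpectrum <- function(x, ...) {
  cat(sprintf("StickSpectrum: %d sticks, %.1f..%.1f cm^-1, total intensity %.4g\n",
              length(x$energies), min(x$energies), max(x$energies),
              x$total_intensity))
  invisible(x)
}

stick_energy <- function(map, v, vp) {
  map$E00_zpe + sum(vp * map$freqs_final) - sum(v * map$freqs_initial)
}

stick_intensity <- function(map, energies, fc2, population = 1,
                            prefactor = TRUE) {
  base <- mu2(map) * population * fc2
  if (prefactor) base * energies else base
}

# Enumerate final-state quanta vectors: at most max_simultaneous modes
# excited, at most max_quanta per mode. Returns an integer matrix
# (rows = vectors) including the all-zero vector.
enumerate_final_vectors <- function(n, max_quanta, max_simultaneous) {
  vecs <- list(matrix(0L, 1, n))
  kmax <- min(max_simultaneous, n)
  for (k in seq_len(kmax)) {
    subs <- utils::combn(n, k)
    grids <- as.matrix(expand.grid(rep(list(seq_len(max_quanta)), k)))
    for (s in seq_len(ncol(subs))) {
      m <- matrix(0L, nrow(grids), n)
      m[, subs[, s]] <- as.integer(grids)
      vecs[[length(vecs) + 1]] <- m
    }
  }
  do.call(rbind, vecs)
}

# Franck-Condon factors |<v|v'>|^2 for a fixed initial vector v over a matrix
# of final vectors, choosing the factorized path for diagonal maps.
fc_factors_for <- function(map, v, finals, tabs = NULL) {
  n <- map$nmodes
  if (map_is_diagonal(map)) {
    if (is.null(tabs)) {
      tabs <- lapply(seq_len(n), function(i)
        fc_table_1d(map, i, max(v), max(finals)))
    }
    amp <- rep(1, nrow(finals))
    for (i in seq_len(n)) {
      amp <- amp * tabs[[i]][v[i] + 1, finals[, i] + 1]
    }
    amp^2
  } else {
    eng <- fc_engine(map)
    apply(finals, 1, function(vp) fc_get(eng, as.integer(v), as.integer(vp)))^2
  }
}

#' Zero-temperature Franck-Condon stick spectrum
#'
#' Enumerates transitions from the vibrational ground state of the initial
#' surface, organized by excitation class (number of simultaneously excited
#' final modes), honoring a per-mode quanta cap and an intensity floor.
#' Every stick carries its initial and final quanta assignment. Stick
#' intensity is `energy * |mu|^2 * FC` by default (`prefactor = FALSE` drops
#' the frequency factor).
#'
#' @param map a `DuschinskyMap` with positive frequencies.
#' @param max_quanta per-mode maximum final quanta (default 10).
#' @param max_simultaneous maximum number of simultaneously excited final
#'   modes (default 4).
#' @param floor sticks below `floor` times the strongest stick are dropped
#'   from the output (default 1e-8).
#' @param completeness_floor warn if the captured fraction of the theoretical
#'   total FC weight falls below this (default 0.99).
#' @param prefactor multiply intensities by the transition wavenumber.
#' @return a `StickSpectrum`.
#' @export
sticks_zero_T <- function(map, max_quanta = 10, max_simultaneous = 4,
                          floor = 1e-8, completeness_floor = 0.99,
                          prefactor = TRUE) {
  stopifnot(inherits(map, "DuschinskyMap"))
  n <- map$nmodes
  finals <- enumerate_final_vectors(n, max_quanta, max_simultaneous)
  v0 <- rep(0L, n)
  fc2 <- fc_factors_for(map, v0, finals)
  captured <- sum(fc2)
  if (captured < completeness_floor) {
    warning(sprintf("truncation captures only %.4f of the FC weight", captured))
  }
  energies <- map$E00_zpe + as.numeric(finals %*% map$freqs_final)
  keep <- fc2 >= floor * max(fc2)
  intens <- stick_intensity(map, energies[keep], fc2[keep],
                            prefactor = prefactor)
  stick_spectrum(energies[keep], intens,
                 matrix(0L, sum(keep), n), finals[keep, , drop = FALSE],
                 meta = list(model = map$model, temperature = 0,
                             max_quanta = max_quanta,
                             max_simultaneous = max_simultaneous,
                             prefactor = prefactor,
                             captured_fraction = captured))
}

#' Boltzmann populations of initial vibrational levels
#'
#' Per-mode geometric distributions `p_v = (1 - q) q^v`, `q = exp(-w/kT)`,
#' multiplied over modes. Quanta vectors whose population falls below `floor`
#' (of the total, which is 1) are pruned; the kept fraction is reported as
#' the renormalization factor.
#'
#' @param freqs mode wavenumbers, cm^-1 (positive).
#' @param T temperature, K (>= 0).
#' @param floor pruning threshold on the vector population.
#' @return list: `vectors` (integer matrix), `populations`, `kept_fraction`.
#' @export
boltzmann_populations <- function(freqs, T, floor = 1e-6) {
  if (T < 0) stop("temperature must be >= 0")
  n <- length(freqs)
  if (any(freqs <= 0)) stop("frequencies must be positive")
  if (T == 0) {
    return(list(vectors = matrix(0L, 1, n), populations = 1,
                kept_fraction = 1))
  }
  q <- exp(-freqs / (.const$kB_cm1 * T))
  p0 <- prod(1 - q)
  # DFS over modes; population is monotone decreasing in every quantum, so
  # pruning at `floor` is exact.
  vecs <- list(); pops <- numeric(0)
  rec <- function(i, v, p) {
    if (i > n) {
      vecs[[length(vecs) + 1]] <<- v
      pops[length(pops) + 1] <<- p
      return()
    }
    vi <- 0L
    repeat {
      pv <- p * q[i]^vi
      if (pv < floor) break
      v[i] <- vi
      rec(i + 1L, v, pv)
      vi <- vi + 1L
      if (q[i] == 0) break
    }
  }
  rec(1L, integer(n), p0)
  vectors <- do.call(rbind, vecs)
  list(vectors = vectors, populations = pops, kept_fraction = sum(pops))
}

#' Finite-temperature Franck-Condon stick spectrum
#'
#' Sums population-weighted hot-band enumerations over the thermally
#' populated initial vectors from [boltzmann_populations()]. At `T = 0` this
#' reduces exactly to [sticks_zero_T()].
#'
#' @inheritParams sticks_zero_T
#' @param T temperature, K.
#' @param population_floor pruning threshold for initial-state populations.
#' @return a `StickSpectrum` whose sticks retain both quanta vectors.
#' @export
sticks_thermal <- function(map, T, max_quanta = 10, max_simultaneous = 4,
                           floor = 1e-8, population_floor = 1e-6,
                           prefactor = TRUE) {
  stopifnot(inherits(map, "DuschinskyMap"))
  n <- map$nmodes
  pops <- boltzmann_populations(map$freqs_initial, T, population_floor)
  if (pops$kept_fraction < 0.95) {
    warning(sprintf("population floor excludes %.1f%% of the thermal population",
                    100 * (1 - pops$kept_fraction)))
  }
  # thermally hot modes may need more final quanta than cold ones
  vmax_init <- max(pops$vectors)
  finals <- enumerate_final_vectors(n, max_quanta, max_simultaneous)
  tabs <- if (map_is_diagonal(map)) {
    lapply(seq_len(n), function(i) fc_table_1d(map, i, vmax_init, max_quanta))
  } else NULL
  eng <- if (!map_is_diagonal(map)) fc_engine(map) else NULL
  en_list <- list(); in_list <- list(); iv_list <- list(); fv_list <- list()
  for (r in seq_len(nrow(pops$vectors))) {
    v <- pops$vectors[r, ]
    p <- pops$populations[r]
    if (!is.null(tabs)) {
      fc2 <- fc_factors_for(map, v, finals, tabs)
    } else {
      fc2 <- apply(finals, 1, function(vp)
        fc_get(eng, as.integer(v), as.integer(vp)))^2
    }
    energies <- map$E00_zpe + as.numeric(finals %*% map$freqs_final) -
      sum(v * map$freqs_initial)
    w <- p * fc2
    keep <- w > 0
    en_list[[r]] <- energies[keep]
    in_list[[r]] <- stick_intensity(map, energies[keep], fc2[keep],
                                    population = p, prefactor = prefactor)
    iv_list[[r]] <- matrix(rep(as.integer(v), sum(keep)), ncol = n,
                           byrow = TRUE)
    fv_list[[r]] <- finals[keep, , drop = FALSE]
  }
  energies <- unlist(en_list)
  intens <- unlist(in_list)
  keep <- intens >= floor * max(intens)
  stick_spectrum(energies[keep], intens[keep],
                 do.call(rbind, iv_list)[keep, , drop = FALSE],
                 do.call(rbind, fv_list)[keep, , drop = FALSE],
                 meta = list(model = map$model, temperature = T,
                             max_quanta = max_quanta,
                             max_simultaneous = max_simultaneous,
                             prefactor = prefactor,
                             kept_population = pops$kept_fraction))
}

#' Fraction of fundamental bands in a stick spectrum
#'
#' A fundamental is a stick with exactly one final mode excited by exactly
#' one quantum, starting from the vibrational ground initial state. The
#' count fraction is taken over the non-0-0 sticks; the intensity fraction
#' over the total intensity of all sticks.
#'
#' @param sticks a `StickSpectrum`.
#' @return list with `count_fraction` and `intensity_fraction`.
#' @export
fundamental_fraction <- function(sticks) {
  stopifnot(inherits(sticks, "StickSpectrum"))
  if (!length(sticks$energies)) stop("empty stick spectrum")
  cold <- rowSums(sticks$init_quanta) == 0
  nq <- rowSums(sticks$final_quanta)
  nmodes_exc <- rowSums(sticks$final_quanta > 0)
  fund <- cold & nq == 1 & nmodes_exc == 1
  non00 <- !(cold & nq == 0)
  list(
    count_fraction = if (any(non00)) sum(fund) / sum(non00) else 0,
    intensity_fraction = sum(sticks$intensities[fund]) /
      sum(sticks$intensities)
  )
}

quanta_label <- function(v, vp, one_based = TRUE) {
  off <- if (one_based) 1L else 0L
  fmt <- function(q) {
    idx <- which(q > 0)
    if (!length(idx)) return("0")
    paste(sprintf("%d^%d", idx - 1L + off, q[idx]), collapse = "*")
  }
  if (sum(v) == 0 && sum(vp) == 0) return("0-0")
  lab <- fmt(vp)
  if (sum(v) > 0) lab <- paste0(lab, "<-", fmt(v))
  lab
}

#' Ranked assignment report of a stick spectrum
#'
#' Top-n sticks by intensity with field-style transition labels (`"3^1"` for
#' a fundamental of mode 3, `"3^1*81^1"` for a combination band, suffix
#' `"<-..."` for hot bands) and energies relative to the 0-0 line. Ties in
#' intensity are broken toward lower transition energy, then lexicographic
#' quanta.
#'
#' @param sticks a `StickSpectrum`.
#' @param top_n number of rows to return.
#' @param one_based label modes 1-based (default) or 0-based.
#' @return data.frame: rank, label, energy_cm1, relative_energy_cm1, intensity.
#' @export
assignment_report <- function(sticks, top_n = 10, one_based = TRUE) {
  stopifnot(inherits(sticks, "StickSpectrum"))
  if (!length(sticks$energies)) stop("empty stick spectrum")
  lex <- apply(cbind(sticks$init_quanta, sticks$final_quanta), 1, paste,
               collapse = ",")
  ord <- order(-sticks$intensities, sticks$energies, lex)
  top <- utils::head(ord, top_n)
  e00 <- min(sticks$energies[rowSums(sticks$init_quanta) == 0 &
                               rowSums(sticks$final_quanta) == 0],
             sticks$energies)
  labels <- vapply(top, function(i)
    quanta_label(sticks$init_quanta[i, ], sticks$final_quanta[i, ],
                 one_based), "")
  data.frame(rank = seq_along(top), label = labels,
             energy_cm1 = sticks$energies[top],
             relative_energy_cm1 = sticks$energies[top] - e00,
             intensity = sticks$intensities[top])
}
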