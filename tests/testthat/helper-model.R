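# Shared fixtures: one wild-type kinetic state at zero force, reused across
# test files to avoid recomputing the density pipeline.
wt_params <- motor_params()
wt_lattice <- actin_lattice()
wt_rates <- kinetic_rates()

wt_kinetics <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- myov_kinetics(wt_params, load_force(0),
                                                wt_rates, wt_lattice)
    cache
  }
})

# count well-separated local maxima of a 2D projection: the matrix is
# lightly smoothed (3x3 boxcar), candidate maxima above frac*max are found,
# and two candidates count as one peak unless the ridge between them dips
# below saddle_frac of the lower one
count_projection_peaks <- function(pr, frac = 0.25, saddle_frac = 0.7,
                                   n_smooth = 1) {
  m <- pr$values
  for (s in seq_len(n_smooth)) {
    mp <- m
    mp[] <- 0
    nr <- nrow(m); nc <- ncol(m)
    for (di in -1:1) for (dj in -1:1) {
      mp[2:(nr - 1), 2:(nc - 1)] <- mp[2:(nr - 1), 2:(nc - 1)] +
        m[2:(nr - 1) + di, 2:(nc - 1) + dj] / 9
    }
    m <- mp
  }
  thr <- frac * max(m)
  cand <- list()
  for (i in 2:(nrow(m) - 1)) for (j in 2:(ncol(m) - 1)) {
    v <- m[i, j]
    if (v > thr && v >= max(m[(i - 1):(i + 1), (j - 1):(j + 1)]))
      cand[[length(cand) + 1]] <- c(i, j, v)
  }
  if (!length(cand)) return(0)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, 3]), , drop = FALSE]
  keep <- 1
  for (k in seq_len(nrow(cand))[-1]) {
    distinct <- TRUE
    for (kk in keep) {
      n_pts <- 30
      ii <- round(seq(cand[kk, 1], cand[k, 1], length.out = n_pts))
      jj <- round(seq(cand[kk, 2], cand[k, 2], length.out = n_pts))
      ridge_min <- min(m[cbind(ii, jj)])
      if (ridge_min > saddle_frac * min(cand[k, 3], cand[kk, 3])) {
        distinct <- FALSE
        break
      }
    }
    if (distinct) keep <- c(keep, k)
  }
  length(keep)
}
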