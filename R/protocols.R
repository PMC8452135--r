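#' Experimental sampling-protocol plan
#'
#' Deterministic description of a conventional mapping protocol: an ordered
#' set of stimulation loci and a per-locus repeat count. Total stimuli =
#' `nrow(loci) * repeats_per_locus`.
#'
#' @param loci Ordered locus matrix / data frame.
#' @param repeats_per_locus Stimuli delivered at each locus.
#' @param label `"GRID"`, `"RAND"` or `"USRG-replay"`.
#' @param values Optional recorded MEP amplitudes (replay protocols).
#' @return Object of class `"protocol_plan"`.
#' @export
protocol_plan <- function(loci, repeats_per_locus = 1L, label, values = NULL) {
  X <- if (length(loci)) as_loci(loci) else
    matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x1", "x2")))
  stopifnot(repeats_per_locus >= 1L)
  structure(list(loci = X, repeats_per_locus = as.integer(repeats_per_locus),
                 label = label, values = values),
            class = "protocol_plan")
}

#' @export
print.protocol_plan <- function(x, ...) {
  cat(sprintf("%s protocol: %d sites x %d repeats = %d stimuli\n",
              x$label, nrow(x$loci), x$repeats_per_locus,
              n_stimuli(x)))
  invisible(x)
}

#' Total stimulus count of a protocol plan
#' @param plan A [protocol_plan()].
#' @return Integer.
#' @export
n_stimuli <- function(plan) {
  nrow(plan$loci) * plan$repeats_per_locus
}

#' Regular-grid mapping protocol (GRID)
#'
#' n x n sites centered on the hotspot at fixed pitch, row-major order,
#' each stimulated `repeats` times. The conventional defaults — 7 x 7
#' sites at 1 cm pitch, 6 repeats — give 49 sites and 294 stimuli over a
#' 36 cm^2 patch.
#'
#' @param center Grid center (hotspot), cm.
#' @param n_per_side Sites per side (>= 2).
#' @param pitch Site spacing, cm (> 0).
#' @param repeats Stimuli per site.
#' @return A [protocol_plan()] with label `"GRID"`.
#' @export
make_grid_protocol <- function(center = c(0, 0), n_per_side = 7L,
                               pitch = 1, repeats = 6L) {
  stopifnot(n_per_side >= 2L, pitch > 0)
  center <- as.numeric(center)
  off <- (seq_len(n_per_side) - 1 - (n_per_side - 1) / 2) * pitch
  X <- cbind(x1 = rep(center[1] + off, each = n_per_side),
             x2 = rep(center[2] + off, times = n_per_side))
  protocol_plan(X, repeats_per_locus = repeats, label = "GRID")
}

#' Randomized mapping protocol (RAND)
#'
#' Anchors (the four grid corners and the hotspot) followed by `n_random`
#' seeded uniform-random sites over the domain, one stimulus each. The
#' conventional 289 random sites give 294 total.
#'
#' @param corners 4 x 2 matrix of corner loci, cm.
#' @param hotspot Hotspot locus, cm.
#' @param n_random Number of random sites (>= 0).
#' @param domain A [domain_rect()].
#' @param seed Integer seed.
#' @return A [protocol_plan()] with label `"RAND"`.
#' @export
make_rand_protocol <- function(corners, hotspot, n_random = 289L,
                               domain = domain_rect(0, 6, 0, 6), seed = 1L) {
  stopifnot(n_random >= 0L)
  corners <- as_loci(corners)
  if (nrow(corners) != 4L) stop("corners must contain exactly 4 loci")
  anchors <- rbind(corners, as_loci(hotspot))
  rng <- .local_rng(seed)
  Xr <- if (n_random > 0L) {
    rng$with(cbind(x1 = stats::runif(n_random, domain$x1min, domain$x1max),
                   x2 = stats::runif(n_random, domain$x2min, domain$x2max)))
  } else matrix(numeric(0), 0L, 2L)
  protocol_plan(rbind(anchors, Xr), repeats_per_locus = 1L, label = "RAND")
}

#' Replay a recorded stimulation sequence
#'
#' Reads a sample CSV (columns `x1_cm`, `x2_cm`, `mep_uv`) — typically a
#' user-guided (USRG) session — and returns its loci, in file order, as a
#' protocol plan with the recorded amplitudes attached.
#'
#' @param path Path to the CSV.
#' @return A [protocol_plan()] with label `"USRG-replay"`.
#' @export
replay_protocol <- function(path) {
  samples <- read_samples(path)
  if (nrow(samples) == 0L) warning("empty sample file: empty replay plan")
  protocol_plan(samples, repeats_per_locus = 1L, label = "USRG-replay",
                values = samples$mep_uv)
}

#' Execute a protocol plan against a field oracle
#'
#' Queries the oracle `repeats_per_locus` times at each site (in site order)
#' and aggregates repeats at a site into one sample by their mean — the
#' per-site amplitude map conventionally used for model fitting. The raw
#' per-stimulus table is kept alongside. Replay plans carrying recorded
#' amplitudes use those instead of querying.
#'
#' @param plan A [protocol_plan()].
#' @param oracle A [field_oracle()] (ignored for replay plans with values).
#' @return A [sampling_state()] whose `samples` hold one aggregated row per
#'   site; attribute `"raw"` holds the per-stimulus table.
#' @export
execute_protocol <- function(plan, oracle = NULL) {
  stopifnot(inherits(plan, "protocol_plan"))
  X <- plan$loci
  r <- plan$repeats_per_locus
  if (!is.null(plan$values)) {
    y_site <- as.numeric(plan$values)
    raw <- data.frame(site = seq_len(nrow(X)), x1 = X[, 1], x2 = X[, 2],
                      mep_uv = y_site)
  } else {
    stopifnot(inherits(oracle, "field_oracle"))
    Xrep <- X[rep(seq_len(nrow(X)), each = r), , drop = FALSE]
    y <- query_oracle(oracle, Xrep)
    raw <- data.frame(site = rep(seq_len(nrow(X)), each = r),
                      x1 = Xrep[, 1], x2 = Xrep[, 2], mep_uv = y)
    y_site <- as.numeric(tapply(y, raw$site, mean))
  }
  samples <- data.frame(x1 = X[, 1], x2 = X[, 2], mep_uv = y_site,
                        iteration = seq_len(nrow(X)),
                        criterion_score = NA_real_)
  st <- sampling_state(samples, method = plan$label,
                       budget = nrow(X), initial_count = 0L)
  attr(st, "raw") <- raw
  st
}
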