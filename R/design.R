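#' Build the avoidance-generalization task design
#'
#' Places the stimulus set on the one-dimensional shape-"spikiness" axis
#' (`rho`, bounded in (0,1)): two aversively reinforced stimuli (CS+) at
#' rho 0.25 and 0.75, one safe stimulus (CS-), and four generalization
#' stimuli (GS), one on each side of each CS+ at a perceptual offset
#' `theta` (the individually calibrated 75% discrimination threshold).
#' GS are structurally never reinforced.
#'
#' @param theta Rho offset between each GS and its adjacent CS+. The
#'   default 0.071 is the group-mean discrimination threshold for the
#'   laboratory preset; use [design_preset()] for the online-sample
#'   variant (0.065).
#' @param cs_minus_rho Rho coordinate of the CS-. The default 0.40
#'   places it asymmetrically: nearer one CS+ (0.15 away) than the
#'   other (0.35 away), which is what makes peak-shift asymmetry
#'   measurable.
#' @param axis_flipped If `TRUE`, mirror every rho about 0.5
#'   (counterbalancing of the perceptual axis).
#' @param reinforcement_rate Probability of an aversive outcome on an
#'   unavoided CS+ trial (default 0.8).
#' @param avoid_cost Cost per avoidance decision on the outcome scale
#'   (default 0.2).
#' @param n_blocks Number of task blocks (default 5).
#' @param trials_per_block Named counts of presentations per stimulus
#'   of each role per block; the default ratio 10 CS- : 10 per CS+ :
#'   2 per GS gives 38 trials per block.
#'
#' @return An object of class `avoid_design`: a list with a `stimuli`
#'   tibble (`label`, `rho`, `role`, `adjacent_cs_plus`) and the design
#'   constants.
#' @export
#' @examples
#' d <- build_design()
#' d$stimuli
build_design <- function(theta = 0.071,
                         cs_minus_rho = 0.40,
                         axis_flipped = FALSE,
                         reinforcement_rate = 0.8,
                         avoid_cost = 0.2,
                         n_blocks = 5,
                         trials_per_block = c(CS_PLUS = 10, CS_MINUS = 10, GS = 2)) {
  stopifnot(is.numeric(theta), length(theta) == 1L,
            is.numeric(cs_minus_rho), length(cs_minus_rho) == 1L)
  if (reinforcement_rate < 0 || reinforcement_rate > 1) {
    abort("`reinforcement_rate` must lie in [0, 1].")
  }
  if (avoid_cost < 0) abort("`avoid_cost` must be non-negative.")
  if (theta <= 0) abort("`theta` must be positive.")

  cs_plus_rho <- c(0.25, 0.75)
  stimuli <- tibble::tibble(
    label = c("CSplus1", "CSplus2", "CSminus",
              "GS1lo", "GS1hi", "GS2lo", "GS2hi"),
    rho = c(cs_plus_rho, cs_minus_rho,
            cs_plus_rho[1] - theta, cs_plus_rho[1] + theta,
            cs_plus_rho[2] - theta, cs_plus_rho[2] + theta),
    role = c("CS_PLUS", "CS_PLUS", "CS_MINUS", rep("GS", 4L)),
    adjacent_cs_plus = c(NA, NA, NA,
                         "CSplus1", "CSplus1", "CSplus2", "CSplus2")
  )

  if (any(stimuli$rho <= 0) || any(stimuli$rho >= 1)) {
    abort("Invalid design: a stimulus falls outside the open interval (0, 1).")
  }
  if (min(dist(stimuli$rho)) < 1e-6) {
    abort("Invalid design: two stimuli are closer than 1e-6 on the rho axis.")
  }
  if (axis_flipped) stimuli$rho <- 1 - stimuli$rho

  structure(
    list(
      stimuli = stimuli,
      theta = theta,
      reinforcement_rate = reinforcement_rate,
      avoid_cost = avoid_cost,
      n_blocks = n_blocks,
      trials_per_block = trials_per_block,
      axis_flipped = axis_flipped
    ),
    class = "avoid_design"
  )
}

#' Preset task designs
#'
#' @param preset `"fmri"` (laboratory sample; theta 0.071) or `"amt"`
#'   (online sample; theta 0.065 for all participants).
#' @param ... Overrides passed on to [build_design()].
#' @return An `avoid_design`.
#' @export
design_preset <- function(preset = c("fmri", "amt"), ...) {
  preset <- match.arg(preset)
  theta <- switch(preset, fmri = 0.071, amt = 0.065)
  dots <- list(...)
  if (is.null(dots$theta)) dots$theta <- theta
  do.call(build_design, dots)
}

#' @export
print.avoid_design <- function(x, ...) {
  cat("<avoid_design> ", nrow(x$stimuli), " stimuli, ",
      x$n_blocks, " blocks x ", sum(design_block_counts(x)$n),
      " trials\n", sep = "")
  cat("  theta = ", x$theta,
      ", reinforcement rate = ", x$reinforcement_rate,
      ", avoid cost = ", x$avoid_cost, "\n", sep = "")
  print(x$stimuli)
  invisible(x)
}

# per-stimulus presentation counts per block
design_block_counts <- function(design) {
  tibble::tibble(
    stimulus = design$stimuli$label,
    role = design$stimuli$role,
    n = unname(design$trials_per_block[design$stimuli$role])
  )
}

#' Sequencing constraints for pseudorandom trial orders
#'
#' The task orders trials pseudorandomly to minimise learning about the
#' generalization stimuli: by default no two GS trials may be adjacent
#' within a block and no GS appears in the opening trials of the first
#' block (before any CS value has been acquired).
#'
#' @param no_adjacent_gs Disallow consecutive GS trials within a block.
#' @param gs_lead_in Number of opening trials of block 1 that must be
#'   GS-free.
#' @param max_retries Shuffle attempts per block before giving up.
#' @return A list of class `sequence_constraints`.
#' @export
sequence_constraints <- function(no_adjacent_gs = TRUE,
                                 gs_lead_in = 5L,
                                 max_retries = 1000L) {
  structure(list(no_adjacent_gs = no_adjacent_gs,
                 gs_lead_in = as.integer(gs_lead_in),
                 max_retries = as.integer(max_retries)),
            class = "sequence_constraints")
}

#' Generate a pseudorandom trial sequence
#'
#' Draws a reproducible trial order satisfying the block composition of
#' the design (default: 10 CS-, 10 per CS+, 2 per GS = 38 trials per
#' block over 5 blocks) and schedules the outcome each trial would
#' deliver if unavoided: aversive with probability
#' `design$reinforcement_rate` on CS+ trials, always neutral on CS- and
#' GS trials.
#'
#' @param design An [build_design()] object.
#' @param seed Integer seed; the sequence is byte-reproducible from it.
#' @param constraints A [sequence_constraints()] list.
#' @param quota If `TRUE`, realise the reinforcement rate as an exact
#'   per-block quota (`round(rate * n)` aversive outcomes per CS+ per
#'   block) instead of independent Bernoulli draws.
#' @return A tibble with one row per trial: `block`, `trial` (global
#'   index), `stimulus`, `role`, `rho`, `scheduled_outcome`
#'   (`"aversive"` or `"neutral"`).
#' @export
#' @examples
#' d <- build_design()
#' seq1 <- generate_sequence(d, seed = 1)
#' dplyr::count(seq1, block, role)
generate_sequence <- function(design, seed,
                              constraints = sequence_constraints(),
                              quota = FALSE) {
  stopifnot(inherits(design, "avoid_design"))
  counts <- design_block_counts(design)
  withr_seed(seed, {
    blocks <- lapply(seq_len(design$n_blocks), function(b) {
      labels <- rep(counts$stimulus, counts$n)
      roles <- rep(counts$role, counts$n)
      ord <- shuffle_with_constraints(roles, block = b, constraints)
      tibble::tibble(block = b, stimulus = labels[ord], role = roles[ord])
    })
    trials <- dplyr::bind_rows(blocks)
    trials$trial <- seq_len(nrow(trials))
    trials <- dplyr::left_join(
      trials, design$stimuli[, c("label", "rho")],
      by = c("stimulus" = "label")
    )
    trials$scheduled_outcome <- "neutral"
    csp <- trials$role == "CS_PLUS"
    if (quota) {
      for (b in seq_len(design$n_blocks)) {
        for (s in unique(trials$stimulus[csp])) {
          idx <- which(csp & trials$block == b & trials$stimulus == s)
          n_av <- round(design$reinforcement_rate * length(idx))
          hit <- sample(idx, n_av)
          trials$scheduled_outcome[hit] <- "aversive"
        }
      }
    } else {
      draw <- runif(sum(csp)) < design$reinforcement_rate
      trials$scheduled_outcome[csp][draw] <- "aversive"
    }
    trials[, c("block", "trial", "stimulus", "role", "rho",
               "scheduled_outcome")]
  })
}

# constrained shuffle of within-block trial order; returns a permutation
shuffle_with_constraints <- function(roles, block, constraints) {
  n <- length(roles)
  for (attempt in seq_len(constraints$max_retries)) {
    ord <- sample.int(n)
    r <- roles[ord]
    if (constraints$no_adjacent_gs &&
        any(r[-1] == "GS" & r[-n] == "GS")) next
    if (block == 1L && constraints$gs_lead_in > 0L &&
        any(r[seq_len(min(constraints$gs_lead_in, n))] == "GS")) next
    return(ord)
  }
  abort(paste0("Could not satisfy sequencing constraints in block ", block,
               " after ", constraints$max_retries, " attempts",
               " (rules: no adjacent GS, GS-free lead-in)."))
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
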