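#' @include AllClasses.R
NULL

# Smooth bump used as the building block of all activity templates.
.bump <- function(p, center, width) exp(-((p - center) / width)^2)

# Per-family envelope over normalized activity phase p in [0, 1]. Families
# get slightly different centers; the secondary bump makes the envelope
# asymmetric in time so that a movement and its time-reversed return phase
# ('a' vs 'b' variants) produce different templates.
.familyEnvelope <- function(p, family) {
  ctr <- 0.25 + 0.04 * family
  .bump(p, ctr, 0.15) + 0.45 * .bump(p, ctr + 0.30, 0.10)
}

# Signed envelope for acceleration (acceleration followed by deceleration).
.familySignedEnvelope <- function(p, family) {
  ctr <- 0.25 + 0.04 * family
  .bump(p, ctr, 0.15) - 0.6 * .bump(p, ctr + 0.28, 0.12)
}

# Muscle activation weights per family: quadriceps, biceps femoris,
# tibialis anterior, gastrocnemius (one value per muscle, same for both legs
# except stepping, which is asymmetric).
.emgFamilyWeights <- rbind(
  c(1.00, 0.30, 0.50, 0.40),  # squat: knee extensors dominate
  c(0.80, 0.50, 0.30, 0.20),  # sit/stand
  c(0.20, 0.20, 0.60, 0.70),  # reach forward: ankle stabilizers
  c(0.30, 0.20, 0.40, 0.90),  # reach up: calf raise component
  c(0.40, 0.90, 0.30, 0.50),  # trunk bend: hamstrings
  c(0.50, 0.40, 0.60, 0.50))  # step (swing-leg weights; stance leg stronger)
.emgStepStance <- c(1.00, 0.70, 0.90, 0.80)

# Plantar region loading weights per family: heel, center, front (per foot).
.pressureFamilyWeights <- rbind(
  c(0.10, 0.30, 0.80),  # squat: forefoot loading
  c(0.60, 0.20, 0.10),  # sit/stand: heel dominated
  c(0.05, 0.20, 0.50),  # reach forward
  c(0.10, 0.15, 0.65),  # reach up (toe raise)
  c(0.70, 0.30, 0.40),  # trunk bend
  c(0.40, 0.20, 0.30))  # step (swing foot; stance foot stronger)
.pressureStepStance <- c(0.90, 0.40, 0.60)

# Sternum acceleration direction (X forward, Y lateral, Z vertical).
.accFamilyDirections <- rbind(
  c(0.20, 0.00, 1.00),
  c(0.60, 0.10, 0.70),
  c(1.00, 0.00, 0.30),
  c(0.40, 0.20, 1.00),
  c(0.90, 0.10, 0.60),
  c(0.70, 0.60, 0.40))

.emgChannels <- c("EL1", "EL2", "EL3", "EL4", "ER1", "ER2", "ER3", "ER4")
.pressureRegions <- c("L1", "L2", "L3", "R1", "R2", "R3")
.accChannels <- c("X", "Y", "Z")

.parseActivity <- function(activity) {
  if (!is.character(activity) || length(activity) != 1L ||
      !activity %in% activityLevels())
    stop("unknown activity label: ", paste(activity, collapse = ", "))
  list(family = as.integer(substr(activity, 1L, 1L)),
       variant = substr(activity, 2L, 2L))
}

#' Deterministic per-activity sensor templates
#'
#' Returns the template function of one activity on one sensor: a bounded,
#' channel-complete signal over the normalized activity phase
#' \eqn{p \in [0, 1]}. Templates are piecewise-smooth bump functions encoding
#' only the qualitative structure of each movement (which muscles fire, which
#' foot regions load, which way the sternum accelerates); no biomechanical
#' fidelity is claimed. The return phase of a movement (`b` variants) is the
#' time reversal of the forward phase, except for stepping (6a/6b) which is
#' the left/right mirror with the stepping-side channels leading in time.
#' All 12 templates are pairwise distinct on every sensor.
#'
#' @param activity one of the labels from [activityLevels()].
#' @param sensor `"emg"` (8 channels), `"pressure"` (64 sensels, filled
#'   region-wise using [defaultPressureLayout()]) or `"acc"` (3 channels).
#' @return `function(p)` mapping a phase vector to a `length(p) x nchannel`
#'   matrix with named columns.
#' @examples
#' f <- activityArchetype("1a", "emg")
#' dim(f(seq(0, 1, length.out = 5)))
#' @export
activityArchetype <- function(activity,
                              sensor = c("emg", "pressure", "acc")) {
  sensor <- match.arg(sensor)
  act <- .parseActivity(activity)
  fam <- act$family
  reversed <- act$variant == "b" && fam != 6L
  stepLeft <- fam == 6L && act$variant == "b"

  if (sensor == "emg") {
    wSwing <- .emgFamilyWeights[fam, ]
    if (fam == 6L) {
      wL <- if (stepLeft) .emgStepStance else wSwing
      wR <- if (stepLeft) wSwing else .emgStepStance
    } else {
      wL <- wR <- wSwing
    }
    weights <- c(wL, wR)
    lead <- if (fam == 6L) {
      if (stepLeft) c(rep(0.08, 4L), rep(-0.08, 4L))
      else c(rep(-0.08, 4L), rep(0.08, 4L))
    } else rep(0, 8L)
    chn <- .emgChannels
    env <- .familyEnvelope
  } else if (sensor == "pressure") {
    wSwing <- .pressureFamilyWeights[fam, ]
    if (fam == 6L) {
      wL <- if (stepLeft) .pressureStepStance else wSwing
      wR <- if (stepLeft) wSwing else .pressureStepStance
    } else {
      wL <- wR <- wSwing
    }
    weights <- c(wL, wR)
    lead <- if (fam == 6L) {
      if (stepLeft) c(rep(0.08, 3L), rep(-0.08, 3L))
      else c(rep(-0.08, 3L), rep(0.08, 3L))
    } else rep(0, 6L)
    chn <- .pressureRegions
    env <- .familyEnvelope
  } else {
    weights <- .accFamilyDirections[fam, ]
    if (stepLeft) weights[2L] <- -weights[2L]
    lead <- rep(0, 3L)
    chn <- .accChannels
    env <- .familySignedEnvelope
  }

  force(fam); force(reversed)
  fn <- function(p) {
    stopifnot(is.numeric(p))
    q <- if (reversed) 1 - p else p
    out <- vapply(seq_along(weights), function(ch)
      weights[ch] * env(q + lead[ch], fam), numeric(length(p)))
    out <- matrix(out, nrow = length(p), ncol = length(weights))
    colnames(out) <- chn
    if (sensor == "pressure") {
      layout <- defaultPressureLayout()
      out <- out[, layout, drop = FALSE]
      colnames(out) <- names(layout)
    }
    out
  }
  fn
}

#' Oscillation axes of an activity's silhouette motion
#'
#' Each activity moves the synthetic silhouette along two successive
#' oscillation axes (first and second half of the repetition), given as
#' display-space angles in degrees (x rightward, y upward on screen, axes
#' modulo 180). The 12 (first, second) axis pairs are pairwise distinct,
#' and the return phase of a movement swaps the two axes.
#'
#' @param activity one of the labels from [activityLevels()].
#' @return numeric length-2 vector of axis angles in degrees.
#' @examples
#' videoTrajectory("1a"); videoTrajectory("1b")
#' @export
videoTrajectory <- function(activity) {
  .parseActivity(activity)
  axes <- list("1a" = c(90, 0),   "1b" = c(0, 90),
               "2a" = c(45, 135), "2b" = c(135, 45),
               "3a" = c(0, 45),   "3b" = c(45, 0),
               "4a" = c(90, 135), "4b" = c(135, 90),
               "5a" = c(0, 135),  "5b" = c(135, 0),
               "6a" = c(45, 90),  "6b" = c(90, 45))
  axes[[activity]]
}

#' Default sensel-to-region layout of the pressure insoles
#'
#' Each insole carries 32 sensels arranged as a 4-column by 8-row grid
#' (row 1 at the toes). Rows 1--3 map to the front region, rows 4--5 to the
#' center, rows 6--8 to the heel. Sensels 1--32 belong to the left foot
#' (column-major over the grid), 33--64 to the right foot. Regions are coded
#' 1 = heel, 2 = center, 3 = front per foot, following the L1/L2/L3,
#' R1/R2/R3 naming.
#'
#' @return Integer vector of length 64 with values 1..6 indexing the regions
#'   `c("L1","L2","L3","R1","R2","R3")`; names give the region label of each
#'   sensel.
#' @examples
#' table(names(defaultPressureLayout()))
#' @export
defaultPressureLayout <- function() {
  rowRegion <- c(3L, 3L, 3L, 2L, 2L, 1L, 1L, 1L)  # front / center / heel
  oneFoot <- rep(rowRegion, times = 4L)           # 4 columns, column-major
  layout <- c(oneFoot, oneFoot + 3L)
  names(layout) <- .pressureRegions[layout]
  layout
}
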