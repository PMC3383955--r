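#' @include AllClasses.R
NULL

#' Index of difficulty of an aimed movement
#'
#' Computes the Fitts index of difficulty \code{ID = log2(2 * A / W)} in bits,
#' where \code{A} is the movement amplitude (centre-to-centre distance) and
#' \code{W} the target width. Vectorized; amplitude and width are recycled to
#' a common length.
#'
#' @param amplitudeCm movement amplitude in cm, positive.
#' @param widthCm target width in cm, positive.
#' @return Numeric vector of IDs in bits. Strictly increasing in amplitude and
#'   strictly decreasing in width; adding one bit doubles the amplitude at
#'   fixed width.
#' @examples
#' computeID(8, 4)   # 2
#' computeID(32, 4)  # 4, the hardest cell of the default design
#' @export
computeID <- function(amplitudeCm, widthCm) {
  if (any(!is.finite(amplitudeCm)) || any(!is.finite(widthCm)) ||
      any(amplitudeCm <= 0) || any(widthCm <= 0))
    stop("computeID: amplitude and width must be positive and finite")
  log2(2 * amplitudeCm / widthCm)
}

#' Default trial timing of the pre-cued tapping task
#'
#' Fixation dot for 500 ms, a 150 ms cue, a 1000 ms foreperiod between cue
#' onset and go onset, a 150 ms go signal, and a 4000 ms trial period (so a
#' 63-trial block lasts 4 min 12 s).
#'
#' @return Named list of timing constants in ms.
#' @export
defaultTiming <- function() {
  list(fixationMs = 500, cueMs = 150, foreperiodMs = 1000, goMs = 150,
       trialPeriodMs = 4000)
}

#' Build the factorial design of the pre-cued tapping experiment
#'
#' Constructs the full trial plan: for every target width and ID level the
#' movement amplitude is obtained by inverting the ID formula,
#' \code{A = W * 2^ID / 2}. Within a block the width is constant and the cue
#' types (one directional cue per ID level and hand, plus a no-go cue) are
#' assigned with equal probability; the number of trials per block is derived
#' from the block duration and the trial period.
#'
#' @param widths target widths in cm (default \code{c(1, 2, 4)}).
#' @param ids ID levels in bits (default \code{c(2, 3, 4)}), non-negative.
#' @param timing trial timing, see [defaultTiming()].
#' @param nBlocks total number of blocks (default 12; a multiple of
#'   \code{length(widths)}).
#' @param blockDurationS block duration in seconds (default 252, i.e.
#'   4 min 12 s, giving 63 trials at the default 4 s trial period).
#' @return An [ExperimentDesign-class].
#' @examples
#' d <- buildDesign()
#' subset(designCells(d), width == 1)$amplitude  # 2 4 8
#' @export
buildDesign <- function(widths = c(1, 2, 4), ids = c(2, 3, 4),
                        timing = defaultTiming(), nBlocks = 12L,
                        blockDurationS = 252) {
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("buildDesign: widths must be positive")
  if (any(!is.finite(ids)) || any(ids < 0))
    stop("buildDesign: IDs must be non-negative")
  widths <- sort(widths)
  ids <- sort(ids)
  cells <- expand.grid(width = widths, id = ids, KEEP.OUT.ATTRS = FALSE)
  cells$amplitude <- cells$width * 2^cells$id / 2
  cells$idLevel <- match(cells$id, ids)
  cells <- cells[order(cells$width, cells$id), ]
  rownames(cells) <- NULL
  trialsPerBlock <- blockDurationS * 1000 / timing$trialPeriodMs
  if (abs(trialsPerBlock - round(trialsPerBlock)) > 1e-9)
    stop("buildDesign: block duration is not a whole number of trial periods")
  cueTypes <- c(as.vector(t(outer(seq_along(ids), c("left", "right"),
                                  function(i, h) paste0("id", i, "_", h)))),
                "nogo")
  new("ExperimentDesign",
      widths = widths, ids = ids, cells = cells,
      hands = c("left", "right"), cueTypes = cueTypes,
      nBlocks = as.integer(nBlocks),
      trialsPerBlock = as.integer(round(trialsPerBlock)),
      blockDurationS = blockDurationS, timing = timing)
}

#' Design cells accessor
#'
#' @param design an [ExperimentDesign-class].
#' @return data.frame with one row per width x ID cell (columns \code{width},
#'   \code{id}, \code{amplitude}, \code{idLevel}).
#' @export
designCells <- function(design) {
  stopifnot(is(design, "ExperimentDesign"))
  design@cells
}

#' Probability of each cue type within a block
#'
#' @param design an [ExperimentDesign-class].
#' @return Single numeric, \code{1 / number of cue types} (1/7 = 14.3% for
#'   the default design).
#' @export
cueTypeProbability <- function(design) {
  stopifnot(is(design, "ExperimentDesign"))
  1 / length(design@cueTypes)
}
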