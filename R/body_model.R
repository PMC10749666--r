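#' Subject anthropometrics
#'
#' Validates and packages the anthropometric measures every normalization in
#' the metric set relies on: leg length (step length/width, XCoM pendulum
#' scaling), foot length (A-P CoP progression), and height and mass
#' (angular momenta, V-CoM).
#'
#' @param height_m standing height in metres.
#' @param mass_kg body mass in kilograms.
#' @param leg_length_m greater-trochanter-to-floor leg length in metres.
#'   Default `0.53 * height_m`, a standard proportion.
#' @param foot_length_m foot length in metres. Default `0.152 * height_m`.
#' @param affected_side which side carries the prosthesis, `"left"` or
#'   `"right"`.
#' @return An object of class `anthropometrics`.
#' @examples
#' anthropometrics(1.67, 86, affected_side = "left")
#' @export
anthropometrics <- function(height_m, mass_kg,
                            leg_length_m = 0.53 * height_m,
                            foot_length_m = 0.152 * height_m,
                            affected_side = c("left", "right")) {
  affected_side <- match.arg(affected_side)
  for (v in c(height_m, mass_kg, leg_length_m, foot_length_m)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("anthropometrics: all measures must be single positive numbers",
           call. = FALSE)
  }
  if (leg_length_m >= height_m)
    stop("anthropometrics: leg length must be smaller than height", call. = FALSE)
  if (foot_length_m >= leg_length_m)
    stop("anthropometrics: foot length must be smaller than leg length", call. = FALSE)
  structure(
    list(height = height_m, mass = mass_kg, leg_length = leg_length_m,
         foot_length = foot_length_m, affected_side = affected_side),
    class = "anthropometrics")
}

#' @export
print.anthropometrics <- function(x, ...) {
  cat(sprintf(
    "<anthropometrics> height %.2f m, mass %.1f kg, leg %.3f m, foot %.3f m, prosthetic side: %s\n",
    x$height, x$mass, x$leg_length, x$foot_length, x$affected_side))
  invisible(x)
}

#' Canonical 14-segment naming
#'
#' Head+neck, trunk, and bilateral upper arms, forearms, hands, thighs,
#' shanks and feet.
#' @return character vector of the 14 segment names.
#' @export
segment_names <- function() {
  c("head_neck", "trunk",
    "upper_arm_L", "upper_arm_R", "forearm_L", "forearm_R",
    "hand_L", "hand_R", "thigh_L", "thigh_R",
    "shank_L", "shank_R", "foot_L", "foot_R")
}

#' Read an anthropometric segment-parameter table
#'
#' The table gives, per segment, its mass as a fraction of body mass, its
#' centre of mass as a fraction of segment length from the proximal end, its
#' radius of gyration about the segment CoM as a fraction of segment length,
#' and its length as a fraction of standing height. The packaged default is
#' a Winter/Dempster-style table.
#'
#' @param path CSV path; default the packaged Winter-style table.
#' @return data.frame with columns `segment`, `mass_fraction`,
#'   `com_fraction`, `gyration_fraction`, `length_fraction`.
#' @export
read_segment_table <- function(path = system.file("extdata",
                                                  "segment_parameters_winter.csv",
                                                  package = "gaitstab")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "mass_fraction", "com_fraction",
            "gyration_fraction", "length_fraction")
  if (!all(need %in% names(tab)))
    stop("segment table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}

#' Build a 14-segment sagittal body model
#'
#' Scales a segment-parameter table by the subject's height and mass into
#' per-segment mass, length, CoM offset and sagittal moment of inertia
#' (`I = m (k L)^2` with `k` the radius-of-gyration fraction). Thigh and
#' shank lengths are rescaled so they sum to the measured leg length, and
#' the foot segment length is set to the measured foot length; all other
#' lengths follow the table's height fractions.
#'
#' @param anthro an [anthropometrics()] object.
#' @param table segment-parameter table (see [read_segment_table()]).
#' @param overrides optional named list of per-segment overrides, each a list
#'   with any of `mass`, `length`, `com_fraction`, `inertia` — e.g. measured
#'   prosthetic shank/foot inertial properties.
#' @return A `body_model`: data.frame with one row per segment and columns
#'   `segment`, `mass` (kg), `length` (m), `com_fraction`, `inertia`
#'   (kg m^2), plus attributes `anthro`.
#' @examples
#' bm <- build_body_model(anthropometrics(1.67, 86))
#' sum(bm$mass)  # closes on 86 kg
#' @export
build_body_model <- function(anthro, table = read_segment_table(),
                             overrides = NULL) {
  stopifnot(inherits(anthro, "anthropometrics"))
  segs <- segment_names()
  miss <- setdiff(segs, table$segment)
  if (length(miss))
    stop("segment table is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- table[match(segs, table$segment), ]

  len <- tab$length_fraction * anthro$height
  # tie the leg chain to the measured leg and foot lengths
  leg_idx <- tab$segment %in% c("thigh_L", "thigh_R", "shank_L", "shank_R")
  thigh_fr <- tab$length_fraction[tab$segment == "thigh_L"]
  shank_fr <- tab$length_fraction[tab$segment == "shank_L"]
  scale_leg <- anthro$leg_length / ((thigh_fr + shank_fr) * anthro$height)
  len[leg_idx] <- len[leg_idx] * scale_leg
  len[tab$segment %in% c("foot_L", "foot_R")] <- anthro$foot_length

  model <- data.frame(
    segment = tab$segment,
    mass = tab$mass_fraction * anthro$mass,
    length = len,
    com_fraction = tab$com_fraction,
    inertia = tab$mass_fraction * anthro$mass *
      (tab$gyration_fraction * len)^2,
    stringsAsFactors = FALSE)

  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), segs)
    if (length(bad))
      stop("overrides for unknown segments: ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (nm in names(overrides)) {
      i <- match(nm, model$segment)
      ov <- overrides[[nm]]
      if (!is.null(ov$mass)) model$mass[i] <- ov$mass
      if (!is.null(ov$length)) model$length[i] <- ov$length
      if (!is.null(ov$com_fraction)) model$com_fraction[i] <- ov$com_fraction
      if (!is.null(ov$inertia)) model$inertia[i] <- ov$inertia
    }
  }

  if (any(model$inertia < 0)) stop("negative segment inertia", call. = FALSE)
  closure <- abs(sum(model$mass) - anthro$mass) / anthro$mass
  if (is.null(overrides) && closure > 0.01)
    stop(sprintf("segment masses close on %.2f kg, > 1%% off the %.2f kg total",
                 sum(model$mass), anthro$mass), call. = FALSE)
  attr(model, "anthro") <- anthro
  class(model) <- c("body_model", "data.frame")
  model
}
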