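#' Default stimulus catalogue
#'
#' The catalogue of snake species used by the simulated experiment: 20
#' species split into three morphotype groups (8 cobras, 8 vipers, 4
#' "other" -- two pythons and two colubrids), each photographed in a
#' threatening and a relaxed posture and presented as a horizontal mirror
#' pair, plus one practise slide.
#'
#' @return A data frame with one row per species and columns `species_id`,
#'   `morphotype` (factor: cobra/viper/other) and `taxon` (cobra, viper,
#'   python or colubrid; the python/colubrid split matters for the
#'   presentation-order composition constraint).
#' @export
snake_catalogue <- function() {
  species_id <- c(sprintf("cobra%02d", 1:8),
                  sprintf("viper%02d", 1:8),
                  sprintf("python%02d", 1:2),
                  sprintf("colubrid%02d", 1:2))
  taxon <- c(rep("cobra", 8), rep("viper", 8),
             rep("python", 2), rep("colubrid", 2))
  morphotype <- ifelse(taxon %in% c("python", "colubrid"), "other", taxon)
  data.frame(species_id = species_id,
             morphotype = factor(morphotype, levels = c("cobra", "viper", "other")),
             taxon = taxon,
             stringsAsFactors = FALSE)
}

#' Build the full stimulus set from a species catalogue
#'
#' Every experimental species contributes two stimulus versions: one with
#' the threatening posture on the left and its horizontal mirror with the
#' threat on the right. A single practise slide (non-snake) is appended and
#' flagged; it is shown first and discarded before analysis.
#'
#' @param catalogue Species catalogue as returned by [snake_catalogue()].
#' @param allow_scaled If `FALSE` (default) the catalogue must have the
#'   canonical 8/8/4 cobra/viper/other composition; set `TRUE` to allow
#'   scaled-down catalogues (used by small simulations).
#' @return Data frame of stimulus versions with columns
#'   `stimulus_version_id`, `species_id`, `morphotype`, `taxon`,
#'   `side_of_threat` ("left"/"right") and `is_practise`.
#' @export
build_stimulus_set <- function(catalogue = snake_catalogue(), allow_scaled = FALSE) {
  stopifnot(is.data.frame(catalogue),
            all(c("species_id", "morphotype") %in% names(catalogue)))
  if (anyDuplicated(catalogue$species_id))
    stop("duplicate species_id in catalogue")
  counts <- table(factor(catalogue$morphotype, levels = c("cobra", "viper", "other")))
  if (!allow_scaled && !identical(as.integer(counts), c(8L, 8L, 4L)))
    stop("catalogue must contain 8 cobra, 8 viper and 4 other species ",
         "(use allow_scaled = TRUE for reduced designs)")
  if (is.null(catalogue$taxon)) catalogue$taxon <- as.character(catalogue$morphotype)
  two <- catalogue[rep(seq_len(nrow(catalogue)), each = 2L), , drop = FALSE]
  two$side_of_threat <- rep(c("left", "right"), nrow(catalogue))
  two$stimulus_version_id <- paste0(two$species_id, "_",
                                    ifelse(two$side_of_threat == "left", "L", "R"))
  two$is_practise <- FALSE
  practise <- data.frame(species_id = "practise", morphotype = "other",
                         taxon = "practise", side_of_threat = "left",
                         stimulus_version_id = "practise_L", is_practise = TRUE,
                         stringsAsFactors = FALSE)
  out <- rbind(two[, names(practise)], practise)
  rownames(out) <- NULL
  out
}

#' Screen geometry of the presentation display
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param distance_cm Viewing distance, head to screen.
#' @param dispersion_radius_px Dispersion radius used by the fixation
#'   detector; 23 px corresponds to 0.5 degrees of visual angle at the
#'   default geometry.
#' @return A list of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1366, height_px = 768,
                            distance_cm = 60, dispersion_radius_px = 23) {
  stopifnot(width_px > 0, height_px > 0, dispersion_radius_px > 0)
  structure(list(width_px = as.numeric(width_px),
                 height_px = as.numeric(height_px),
                 distance_cm = as.numeric(distance_cm),
                 dispersion_radius_px = as.numeric(dispersion_radius_px)),
            class = "screen_geometry")
}

#' Construct the three interest areas (AOIs)
#'
#' Left and right AOIs are full-height rectangles at the screen edges, each
#' covering 37% of the screen area; the central AOI is a small square (1%
#' of the screen) centred on the fixation-cross location. The three
#' rectangles are pairwise disjoint and the left/right pair is symmetric
#' about the vertical screen midline. Coordinates use the standard screen
#' convention: origin top-left, x rightward, y downward, 0-based pixels.
#'
#' @param screen A [screen_geometry()].
#' @param side_fraction,central_fraction Area fractions of each lateral AOI
#'   and of the central AOI.
#' @return A list of class `aoi_set` with elements `left`, `right`,
#'   `central`, each a rectangle `c(x0, y0, x1, y1)`, plus the screen.
#'   Boundary-inclusion rules are chosen so the right AOI is the exact
#'   mirror image of the left under the pixel mirror `x -> width - 1 - x`:
#'   left membership is `x0 <= x < x1`, right membership `x0 < x <= x1`,
#'   central membership closed in x and symmetric about `(width - 1) / 2`
#'   (see [assign_point()]). This makes every AOI label strictly
#'   equivariant under horizontal mirroring of continuous gaze
#'   coordinates.
#' @export
make_aoi_set <- function(screen = screen_geometry(),
                         side_fraction = 0.37, central_fraction = 0.01) {
  w <- screen$width_px; h <- screen$height_px
  side_w <- round(side_fraction * w)
  cen_side <- round(sqrt(central_fraction * w * h))
  if (2 * side_w + cen_side > w - 1)
    stop("screen too small for disjoint AOIs at the requested area fractions")
  mid <- (w - 1) / 2
  aois <- list(
    left    = c(0, 0, side_w, h),
    right   = c(w - 1 - side_w, 0, w - 1, h),
    central = c(mid - cen_side / 2, h / 2 - cen_side / 2,
                mid + cen_side / 2, h / 2 + cen_side / 2))
  af <- vapply(aois, function(r) (r[3] - r[1]) * (r[4] - r[2]), 0) / (w * h)
  if (abs(af[["left"]] - side_fraction) > 0.005 ||
      abs(af[["central"]] - central_fraction) > 0.002)
    stop("AOI area fractions outside tolerance for this screen")
  structure(c(aois, list(screen = screen)), class = "aoi_set")
}

#' Assign a gaze point to an AOI
#'
#' The three AOIs are pairwise disjoint, so at most one label applies.
#' Boundary rules mirror-match left and right (left is closed-open in x,
#' right open-closed; central closed), making the labelling exactly
#' equivariant under [mirror_x()].
#'
#' @param aois An [make_aoi_set()] result.
#' @param x,y Gaze coordinates in pixels (vectors allowed).
#' @return Character vector over `"left"`, `"right"`, `"central"`, `"none"`;
#'   non-finite coordinates map to `"none"`.
#' @export
assign_point <- function(aois, x, y) {
  out <- rep("none", length(x))
  ok <- is.finite(x) & is.finite(y)
  l <- aois$left; r <- aois$right; ce <- aois$central
  yin <- function(rect) ok & y >= rect[2] & y < rect[4]
  out[yin(l) & x >= l[1] & x < l[3]] <- "left"
  out[yin(r) & x > r[1] & x <= r[3]] <- "right"
  out[yin(ce) & x >= ce[1] & x <= ce[3]] <- "central"
  out
}

#' Mirror x-coordinates about the vertical screen midline
#'
#' With the 0-based pixel convention the mirror of column x is
#' `width - 1 - x`.
#' @param x Pixel x-coordinates.
#' @param screen A [screen_geometry()].
#' @export
mirror_x <- function(x, screen = screen_geometry()) {
  screen$width_px - 1 - x
}

#' Build the four presentation orders
#'
#' Each order is a semi-random sequence of the 40 experimental stimulus
#' versions. Ten species (4 cobras, 4 vipers, 1 python, 1 colubrid at the
#' default catalogue) contribute both versions to the first half of the
#' sequence, the remaining species to the second half; within each half the
#' slides are shuffled uniformly. Order 2 is order 1 reversed; orders 3 and
#' 4 replace every slide of orders 1 and 2 with its mirror version.
#'
#' @param stimuli Stimulus set from [build_stimulus_set()].
#' @param seed Integer seed fixing the semi-random base order.
#' @return Data frame with columns `order_id` (1..4), `position` and
#'   `stimulus_version_id`.
#' @export
build_presentation_orders <- function(stimuli, seed = 1L) {
  exp_stim <- stimuli[!stimuli$is_practise, , drop = FALSE]
  species <- unique(exp_stim[, c("species_id", "morphotype", "taxon")])
  if (nrow(species) < 4) stop("need at least 2 species per sequence half")
  set.seed(seed)
  half1 <- unlist(lapply(split(species$species_id, species$taxon), function(ids) {
    k <- ceiling(length(ids) / 2)
    sample(ids, k)
  }), use.names = FALSE)
  half2 <- setdiff(species$species_id, half1)
  versions_of <- function(ids) {
    v <- exp_stim$stimulus_version_id[exp_stim$species_id %in% ids]
    sample(v, length(v))
  }
  order1 <- c(versions_of(half1), versions_of(half2))
  order2 <- rev(order1)
  flip <- function(v) {
    l <- endsWith(v, "_L")
    paste0(sub("_[LR]$", "", v), ifelse(l, "_R", "_L"))
  }
  out <- data.frame(
    order_id = rep(1:4, each = length(order1)),
    position = rep(seq_along(order1), 4),
    stimulus_version_id = c(order1, order2, flip(order1), flip(order2)),
    stringsAsFactors = FALSE)
  out
}
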