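#' Insole sensor layout
#'
#' Describes the ten logical force-sensing-resistor (FSR) channels of a
#' bilateral instrumented insole: five anatomical sites per foot (toe, first
#' metatarsal head, fifth metatarsal head, cuboid, heel). Each site carries a
#' unitless anterior-posterior coordinate with the heel at 0 and the toe at 1,
#' used for centre-of-pressure computation.
#'
#' Channel order is fixed across the package (and in the on-disk recording
#' format): left foot toe, first metatarsal, fifth metatarsal, cuboid, heel,
#' then the right foot in the same site order.
#'
#' @return An object of class `sensor_layout`: a data frame with columns
#'   `channel` (e.g. `"L_toe"`), `foot` (`"L"`/`"R"`), `site` and `ap_coord`.
#' @examples
#' sensor_layout()
#' @export
sensor_layout <- function() {
  sites <- c("toe", "meta1", "meta5", "cuboid", "heel")
  coords <- c(toe = 1.0, meta1 = 0.75, meta5 = 0.65, cuboid = 0.35, heel = 0.0)
  out <- data.frame(
    channel = c(paste0("L_", sites), paste0("R_", sites)),
    foot = rep(c("L", "R"), each = 5L),
    site = rep(sites, 2L),
    ap_coord = rep(unname(coords[sites]), 2L),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sensor_layout", "data.frame")
  validate_sensor_layout(out)
  out
}

validate_sensor_layout <- function(layout) {
  if (nrow(layout) != 10L) stop_arg("sensor layout must have 10 channels, got %d", nrow(layout))
  for (f in c("L", "R")) {
    sub <- layout[layout$foot == f, ]
    if (nrow(sub) != 5L) stop_arg("foot %s must have exactly 5 sites", f)
    # heel -> toe must be strictly increasing in the AP coordinate
    ord <- sub$ap_coord[order(sub$ap_coord)]
    if (any(diff(ord) <= 0)) stop_arg("AP coordinates must be strictly increasing heel to toe")
  }
  invisible(layout)
}

#' Channel names of the standard layout
#' @param layout A [sensor_layout()].
#' @return Character vector of 10 channel names.
#' @export
channel_names <- function(layout = sensor_layout()) layout$channel

# --- stride templates ------------------------------------------------------

# Per-channel loading curves on the normalized 0-100% phase axis. Each site
# is a smooth bump; the heel uses an asymmetric bump with a fast sin^2 rise
# (heel strike is an impact: the rising edge must sit at phase 0) and a
# raised-cosine decay. Remaining sites are raised-cosine bumps centred inside
# stance. Parameters differ per walking condition so that the conditions are
# separable: stair ascent is forefoot-dominant, stair descent has a sharp
# heel/forefoot impact with little midfoot load, ramps are timing-shifted
# variants of level walk.
template_params <- function(wc) {
  # rows: site; cols: onset/center, rise (heel) or NA, width, amplitude
  p <- switch(wc,
    LW = list(
      heel   = c(rise = 4, fall = 36, amp = 1.00),
      cuboid = c(center = 22, width = 18, amp = 0.55),
      meta5  = c(center = 32, width = 20, amp = 0.70),
      meta1  = c(center = 42, width = 20, amp = 0.85),
      toe    = c(center = 55, width = 14, amp = 0.75)
    ),
    SA = list(
      heel   = c(rise = 4, fall = 20, amp = 0.45),
      cuboid = c(center = 18, width = 14, amp = 0.35),
      meta5  = c(center = 30, width = 24, amp = 0.85),
      meta1  = c(center = 40, width = 24, amp = 1.00),
      toe    = c(center = 52, width = 18, amp = 0.95)
    ),
    SD = list(
      heel   = c(rise = 3, fall = 22, amp = 0.90),
      cuboid = c(center = 20, width = 12, amp = 0.20),
      meta5  = c(center = 28, width = 18, amp = 0.90),
      meta1  = c(center = 36, width = 18, amp = 0.95),
      toe    = c(center = 48, width = 14, amp = 0.60)
    ),
    RA = list(
      heel   = c(rise = 5, fall = 30, amp = 0.75),
      cuboid = c(center = 26, width = 18, amp = 0.50),
      meta5  = c(center = 36, width = 20, amp = 0.80),
      meta1  = c(center = 46, width = 20, amp = 0.95),
      toe    = c(center = 58, width = 14, amp = 0.85)
    ),
    RD = list(
      heel   = c(rise = 3, fall = 40, amp = 1.00),
      cuboid = c(center = 18, width = 16, amp = 0.45),
      meta5  = c(center = 26, width = 18, amp = 0.60),
      meta1  = c(center = 34, width = 18, amp = 0.70),
      toe    = c(center = 46, width = 12, amp = 0.50)
    ),
    stop_arg("unknown walking condition '%s'", wc)
  )
  p
}

#' Stride loading template for one walking condition
#'
#' Returns the per-site plantar loading curves that the simulator uses for a
#' single foot over one normalized stride (phase 0-100, anchored at that
#' foot's heel strike). The heel channel rises exactly at phase 0; every
#' channel returns to zero during swing. The left foot reuses the right-foot
#' curves shifted by half a cycle (handled by the simulator, not here).
#'
#' @param wc Walking condition code, one of [wc_levels()].
#' @return An object of class `stride_template`: a function
#'   `f(phase, site, stance_scale = 1, center_shift = 0)` returning the
#'   unit-amplitude load, plus attributes `wc` and `params`.
#' @examples
#' tpl <- stride_template("LW")
#' tpl(0:99, "heel")
#' @export
stride_template <- function(wc) {
  wc <- match.arg(wc, WC_LEVELS)
  params <- template_params(wc)
  f <- function(phase, site, stance_scale = 1, center_shift = 0) {
    p <- params[[site]]
    if (is.null(p)) stop_arg("unknown site '%s'", site)
    ph <- phase %% 100
    if (site == "heel") {
      rise <- p[["rise"]] * stance_scale
      fall <- p[["fall"]] * stance_scale
      x <- ph # onset pinned at phase 0 for every condition
      v <- numeric(length(ph))
      in_rise <- x < rise
      in_fall <- !in_rise & x < rise + fall
      v[in_rise] <- sin(pi / 2 * x[in_rise] / rise)^2
      v[in_fall] <- 0.5 * (1 + cos(pi * (x[in_fall] - rise) / fall))
      p[["amp"]] * v
    } else {
      center <- p[["center"]] * stance_scale + center_shift
      width <- p[["width"]] * stance_scale
      d <- abs(((ph - center + 50) %% 100) - 50) # circular distance
      v <- ifelse(d <= width, 0.5 * (1 + cos(pi * d / width)), 0)
      p[["amp"]] * v
    }
  }
  structure(f, wc = wc, params = params, class = c("stride_template", "function"))
}

# Evaluate the full 10-channel template matrix for a vector of global phases.
# Global phase is anchored at RIGHT heel strike; the left foot is the same
# curve family evaluated at phase + 50.
template_matrix <- function(phase, wc, layout = sensor_layout(),
                            stance_scale = 1, center_shift = NULL) {
  tpl <- stride_template(wc)
  if (is.null(center_shift)) center_shift <- setNames(numeric(10), layout$channel)
  out <- matrix(0, nrow = length(phase), ncol = 10L,
                dimnames = list(NULL, layout$channel))
  for (k in seq_len(10L)) {
    ch <- layout$channel[k]
    local <- if (layout$foot[k] == "L") (phase + 50) %% 100 else phase %% 100
    out[, k] <- tpl(local, layout$site[k], stance_scale = stance_scale,
                    center_shift = center_shift[[ch]])
  }
  out
}

#' Scenario script
#'
#' An ordered list of walking-condition segments, each lasting a whole number
#' of strides, optionally walked in reverse (the segment order is flipped,
#' emulating walking the same course back).
#'
#' @param segments A list of `list(wc =, strides =)` entries, or a data frame
#'   with columns `wc` and `strides`.
#' @param id Character scenario identifier.
#' @param direction `"forward"` or `"reverse"`.
#' @return An object of class `scenario_script`.
#' @examples
#' scenario_script(list(list(wc = "LW", strides = 4), list(wc = "SA", strides = 6)), id = "s2")
#' @export
scenario_script <- function(segments, id = "s1", direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (is.data.frame(segments)) {
    segments <- lapply(seq_len(nrow(segments)), function(i)
      list(wc = segments$wc[i], strides = segments$strides[i]))
  }
  if (length(segments) < 1L) stop_arg("scenario script needs at least one segment")
  seg <- data.frame(
    wc = vapply(segments, function(s) as.character(s$wc), character(1)),
    strides = vapply(segments, function(s) as.numeric(s$strides), numeric(1)),
    stringsAsFactors = FALSE
  )
  if (!all(seg$wc %in% WC_LEVELS)) stop_arg("unknown walking condition in script")
  if (any(seg$strides < 2)) stop_arg("each segment must last at least 2 strides")
  if (any(seg$strides != round(seg$strides))) stop_arg("stride counts must be whole numbers")
  if (direction == "reverse") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  rownames(seg) <- NULL
  structure(list(id = id, direction = direction, segments = seg),
            class = "scenario_script")
}

#' @export
print.scenario_script <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s): %s\n", x$id, x$direction,
              paste(sprintf("%s x%d", x$segments$wc, x$segments$strides), collapse = ", ")))
  invisible(x)
}

#' Default experimental scenarios
#'
#' Three walking courses mirroring a multi-terrain protocol: a level-ground
#' walk, a stair course (level walk, stair ascent, level walk, stair descent,
#' level walk) and a ramp course with the same structure. Stride counts per
#' segment are configurable.
#'
#' @param level_strides Strides per level-walk segment.
#' @param task_strides Strides per stair/ramp segment.
#' @return A named list of three [scenario_script()] objects.
#' @export
default_scenarios <- function(level_strides = 4L, task_strides = 6L) {
  s1 <- scenario_script(list(list(wc = "LW", strides = 3L * level_strides + 2L * task_strides)),
                        id = "s1")
  s2 <- scenario_script(list(
    list(wc = "LW", strides = level_strides), list(wc = "SA", strides = task_strides),
    list(wc = "LW", strides = level_strides), list(wc = "SD", strides = task_strides),
    list(wc = "LW", strides = level_strides)), id = "s2")
  s3 <- scenario_script(list(
    list(wc = "LW", strides = level_strides), list(wc = "RA", strides = task_strides),
    list(wc = "LW", strides = level_strides), list(wc = "RD", strides = task_strides),
    list(wc = "LW", strides = level_strides)), id = "s3")
  list(s1 = s1, s2 = s2, s3 = s3)
}
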