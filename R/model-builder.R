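#' Assemble a 17-segment whole-dog rigid-body parameter model
#'
#' Builds a complete body-segment-parameter model (five axial segments plus
#' left/right pairs of the six limb segments) from a BSP source, records the
#' axis convention per segment, mirrors limb values to both sides, applies
#' the right-brachium frame reversal, and audits whole-body mass closure.
#'
#' Frame convention: box axes per segment with yy the flexion/extension axis,
#' oriented right-to-left for every segment except the crus. The right
#' brachium is measured with its axes reversed; expressing it in the common
#' left-side convention reverses the y axis, which negates the products
#' P_xy and P_yz and leaves diagonals and P_xz unchanged.
#'
#' @param source Either \code{"reference"} (scale the packaged tables via
#'   \code{\link{scale_to_dog}}) or a named list of per-segment entries
#'   (names from \code{\link{segment_names}}), each a list with \code{mass},
#'   \code{length}, \code{com_from_proximal} and \code{tensor} (an
#'   \code{\link{inertia_tensor}} about the CoM).
#' @param body_mass Whole-body mass (kg).
#' @param segment_lengths Optional named numeric vector of segment lengths
#'   (m); defaults to the packaged reference lengths.
#' @param dog_id Free-text identifier stored in the model.
#' @param closure_tol Relative tolerance for the mass-closure audit
#'   (default 2\%); a larger discrepancy warns and is recorded.
#' @return An object of class \code{"dog_model"}: \code{dog_id},
#'   \code{body_mass}, \code{segments} (17 entries keyed
#'   \code{<segment>} or \code{<segment>_<side>}), \code{audit} and
#'   \code{provenance}.
#' @examples
#' m <- build_dog_model("reference", body_mass = 36.8)
#' m$audit$mass_closure
#' @export
build_dog_model <- function(source = "reference", body_mass,
                            segment_lengths = NULL, dog_id = "dog",
                            closure_tol = 0.02) {
  stopifnot(is.finite(body_mass), body_mass > 0)
  names11 <- segment_names()
  get_entry <- if (identical(source, "reference")) {
    provenance <- "packaged reference tables"
    function(seg) {
      len <- if (!is.null(segment_lengths) && seg %in% names(segment_lengths))
        segment_lengths[[seg]] else NULL
      s <- scale_to_dog(seg, body_mass, len)
      list(mass = s$mass, length = s$length,
           com_from_proximal = s$com_from_proximal, tensor = s$tensor)
    }
  } else {
    stopifnot(is.list(source))
    missing <- setdiff(names11, names(source))
    if (length(missing) > 0L)
      stop("assembly error: source missing segment(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    provenance <- "user-supplied BSP set"
    function(seg) source[[seg]]
  }

  segs <- list()
  for (row in seq_len(nrow(bsp_segments()))) {
    seg <- bsp_segments()$segment[row]
    side <- bsp_segments()$side[row]
    e <- get_entry(seg)
    stopifnot(is.list(e),
              all(c("mass", "length", "com_from_proximal", "tensor") %in%
                    names(e)))
    if (e$mass <= 0 || e$com_from_proximal < 0 ||
        e$com_from_proximal > e$length)
      stop("invalid segment entry for ", seg,
           ": need mass > 0 and 0 <= com <= length", call. = FALSE)
    tensor <- e$tensor
    frame <- list(yy = "flexion/extension",
                  orientation = if (seg == "crus") "left-to-right"
                                else "right-to-left",
                  reversed = FALSE)
    if (seg == "brachium" && side == "right") {
      # measured with reversed axes; re-express in the common convention
      tensor <- inertia_tensor(
        tensor$I[["xx"]], tensor$I[["yy"]], tensor$I[["zz"]],
        pxy = -tensor$P[["xy"]], pxz = tensor$P[["xz"]],
        pyz = -tensor$P[["yz"]],
        frame_point = tensor$frame_point, axes_label = tensor$axes_label)
      frame$reversed <- TRUE
    }
    key <- if (side == "none") seg else paste(seg, side, sep = "_")
    segs[[key]] <- list(segment = seg, side = side, mass = e$mass,
                        length = e$length,
                        com_from_proximal = e$com_from_proximal,
                        tensor = tensor, frame = frame)
  }
  total <- sum(vapply(segs, function(s) s$mass, numeric(1)))
  closure <- total / body_mass
  if (abs(closure - 1) > closure_tol)
    warning(sprintf("segment masses sum to %.1f%% of body mass (tolerance %.1f%%)",
                    100 * closure, 100 * closure_tol), call. = FALSE)
  structure(list(
    dog_id = dog_id, body_mass = body_mass, segments = segs,
    audit = list(mass_closure = closure, closure_tol = closure_tol),
    provenance = provenance,
    schema_version = "1.0"), class = "dog_model")
}

#' @export
print.dog_model <- function(x, ...) {
  cat(sprintf("17-segment dog model '%s': body mass %.2f kg, mass closure %.4f\n",
              x$dog_id, x$body_mass, x$audit$mass_closure))
  cat(sprintf("  source: %s\n", x$provenance))
  invisible(x)
}

tensor_to_list <- function(t) {
  list(I_xx = t$I[["xx"]], I_yy = t$I[["yy"]], I_zz = t$I[["zz"]],
       P_xy = t$P[["xy"]], P_xz = t$P[["xz"]], P_yz = t$P[["yz"]],
       frame_point = t$frame_point, axes_label = t$axes_label,
       unit = "kg m^2")
}

tensor_from_list <- function(l) {
  inertia_tensor(l$I_xx, l$I_yy, l$I_zz, l$P_xy, l$P_xz, l$P_yz,
                 frame_point = l$frame_point, axes_label = l$axes_label)
}

#' Export / import a dog model
#'
#' Serialises a \code{\link{build_dog_model}} result to JSON or YAML with
#' units embedded per field, and reads it back losslessly. The segment frame
#' origin convention in the file is the proximal endpoint; tensors are about
#' the segment CoM (use \code{\link{parallel_axis}} to move them).
#'
#' @param model A \code{dog_model}.
#' @param path Output file path; the format is taken from the extension
#'   (\code{.json}, \code{.yaml}/\code{.yml}) unless \code{format} is given.
#' @param format \code{"json"} or \code{"yaml"}.
#' @return \code{export_dog_model}: the path, invisibly.
#'   \code{import_dog_model}: the reconstructed \code{dog_model}.
#' @export
export_dog_model <- function(model, path, format = NULL) {
  stopifnot(inherits(model, "dog_model"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("yaml", "yml")) "yaml" else "json"
  }
  format <- match.arg(format, c("json", "yaml"))
  doc <- list(
    schema_version = model$schema_version,
    dog_id = model$dog_id,
    body_mass_kg = model$body_mass,
    frame_origin = "proximal endpoint",
    provenance = model$provenance,
    audit = model$audit,
    segments = lapply(model$segments, function(s) {
      list(segment = s$segment, side = s$side,
           mass_kg = s$mass, length_m = s$length,
           com_from_proximal_m = s$com_from_proximal,
           frame = s$frame,
           tensor = tensor_to_list(s$tensor))
    }))
  if (format == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(path)
}

#' @rdname export_dog_model
#' @export
import_dog_model <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("yaml", "yml")) "yaml" else "json"
  }
  format <- match.arg(format, c("json", "yaml"))
  doc <- if (format == "json")
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (length(doc$segments) != 17L)
    stop("import error: model must contain exactly 17 segments, found ",
         length(doc$segments), call. = FALSE)
  segs <- lapply(doc$segments, function(s) {
    list(segment = s$segment, side = s$side, mass = s$mass_kg,
         length = s$length_m, com_from_proximal = s$com_from_proximal_m,
         tensor = tensor_from_list(s$tensor),
         frame = list(yy = s$frame$yy, orientation = s$frame$orientation,
                      reversed = isTRUE(s$frame$reversed)))
  })
  names(segs) <- names(doc$segments)
  structure(list(
    dog_id = doc$dog_id, body_mass = doc$body_mass_kg, segments = segs,
    audit = list(mass_closure = doc$audit$mass_closure,
                 closure_tol = doc$audit$closure_tol),
    provenance = doc$provenance,
    schema_version = doc$schema_version), class = "dog_model")
}

#' Whole-body centre of mass of a posed model
#'
#' Mass-weighted CoM given a placement for each segment: the position of the
#' proximal endpoint and a unit direction of the proximal-to-distal axis.
#' The result is independent of per-segment frame-convention choices (the
#' right-brachium reversal only affects tensor products, not masses or CoM
#' positions).
#'
#' @param model A \code{dog_model}.
#' @param placements Named list (same names as \code{model$segments}), each a
#'   list with \code{origin} (3-vector, m) and \code{axis} (unit 3-vector).
#' @return 3-vector whole-body CoM (m).
#' @export
whole_body_com <- function(model, placements) {
  stopifnot(inherits(model, "dog_model"),
            all(names(model$segments) %in% names(placements)))
  num <- c(0, 0, 0); M <- 0
  for (key in names(model$segments)) {
    s <- model$segments[[key]]
    p <- placements[[key]]
    com <- p$origin + s$com_from_proximal * p$axis / sqrt(sum(p$axis^2))
    num <- num + s$mass * com
    M <- M + s$mass
  }
  num / M
}
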