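# ---- Strain-field quantification -------------------------------------------
#
# Reconstructs per-pixel displacement fields between two frames from the
# exported spline parameters and derives finite-strain maps: deformation
# gradient F = I + grad(u), Green-Lagrange tensor E = (FˆT F - I)/2 (second
# order in rotation angle, so rigid rotations are filtered out), the total
# equivalent strain sqrt(Exx^2 + Eyy^2 + 2 Exy^2), and the von Mises
# equivalent strain built from the deviatoric tensor with the 3D trace
# convention (division by 3) applied to the in-plane tensor.

#' Per-pixel displacement field between two frames
#'
#' \code{u(p) = spline_shift(p, frame) - spline_shift(p, reference)}.
#'
#' @param model A [knot_grid_3d()].
#' @param frame,reference Frame indices (1-based).
#' @param nx,ny Raster dimensions.
#' @return An object of class \code{shift_field}: matrices \code{ux},
#'   \code{uy} in pixels plus frame metadata.
#' @export
relative_shift_field <- function(model, frame, reference, nx, ny) {
  NF <- max(model$z_positions)
  for (f in c(frame, reference)) {
    if (f < 1 || f > NF) stop("frame ", f, " out of range [1, ", NF, "]")
  }
  a <- eval_shift_field(model, frame, nx = nx, ny = ny)
  b <- eval_shift_field(model, reference, nx = nx, ny = ny)
  structure(list(ux = a$ux - b$ux, uy = a$uy - b$uy,
                 frame = frame, reference = reference, unit = "pixel"),
            class = "shift_field")
}

# Partial derivatives of a matrix field along x (rows) and y (cols):
# central differences in the interior, one-sided first order at the borders.
grad_xy <- function(m, spacing = 1) {
  nx <- nrow(m); ny <- ncol(m)
  dx <- m
  dx[2:(nx - 1), ] <- (m[3:nx, ] - m[1:(nx - 2), ]) / 2
  dx[1, ] <- m[2, ] - m[1, ]
  dx[nx, ] <- m[nx, ] - m[nx - 1, ]
  dy <- m
  dy[, 2:(ny - 1)] <- (m[, 3:ny] - m[, 1:(ny - 2)]) / 2
  dy[, 1] <- m[, 2] - m[, 1]
  dy[, ny] <- m[, ny] - m[, ny - 1]
  list(dx = dx / spacing, dy = dy / spacing)
}

#' Deformation gradient and Green-Lagrange strain of a displacement field
#'
#' @param field A \code{shift_field} (displacements in pixels).
#' @param pixel_spacing Grid spacing in the same unit as the displacements
#'   (1 when both are pixels), so the gradients are dimensionless.
#' @return An object of class \code{strain_maps} with the deformation
#'   gradient components (\code{F11}, \code{F12}, \code{F21}, \code{F22})
#'   and the symmetric strain components (\code{Exx}, \code{Eyy},
#'   \code{Exy}).
#' @export
deformation_tensors <- function(field, pixel_spacing = 1) {
  gx <- grad_xy(field$ux, pixel_spacing)
  gy <- grad_xy(field$uy, pixel_spacing)
  F11 <- 1 + gx$dx; F12 <- gx$dy
  F21 <- gy$dx;     F22 <- 1 + gy$dy
  Exx <- (F11^2 + F21^2 - 1) / 2
  Eyy <- (F12^2 + F22^2 - 1) / 2
  Exy <- (F11 * F12 + F21 * F22) / 2
  structure(list(F11 = F11, F12 = F12, F21 = F21, F22 = F22,
                 Exx = Exx, Eyy = Eyy, Exy = Exy,
                 total_eq = NULL, vm_eq = NULL),
            class = "strain_maps")
}

#' Total and von Mises equivalent strain maps
#'
#' Total equivalent strain: \code{sqrt(Exx^2 + Eyy^2 + 2 Exy^2)} (axial plus
#' shear magnitude). Von Mises equivalent strain:
#' \code{sqrt(2/3 * ((Exx - tr/3)^2 + (Eyy - tr/3)^2 + 2 Exy^2))} with
#' \code{tr = Exx + Eyy} — the deviatoric part uses the 3D trace convention
#' (division by 3) applied to the in-plane tensor, so a pure in-plane
#' dilation retains a small nonzero von Mises value.
#'
#' @param maps A \code{strain_maps} from [deformation_tensors()].
#' @return The maps with \code{total_eq} and \code{vm_eq} filled.
#' @export
equivalent_strains <- function(maps) {
  stopifnot(inherits(maps, "strain_maps"))
  tr3 <- (maps$Exx + maps$Eyy) / 3
  maps$total_eq <- sqrt(maps$Exx^2 + maps$Eyy^2 + 2 * maps$Exy^2)
  maps$vm_eq <- sqrt(2 / 3 * ((maps$Exx - tr3)^2 + (maps$Eyy - tr3)^2 +
                                2 * maps$Exy^2))
  maps
}

#' @export
print.strain_maps <- function(x, ...) {
  cat("strain_maps:", nrow(x$Exx), "x", ncol(x$Exx), "px")
  if (!is.null(x$vm_eq)) {
    cat(sprintf("; max von Mises %.4g%%, max total %.4g%%",
                100 * max(x$vm_eq), 100 * max(x$total_eq)))
  }
  cat("\n")
  invisible(x)
}

#' Generate strain maps from an exported parameter file
#'
#' Reads refined spline parameters, reconstructs the displacement field of
#' \code{frame} relative to \code{reference} (last vs first frame by
#' default), and writes the ux, uy, total and von Mises equivalent strain
#' maps as float MRC images plus a text summary (max/mean of each map;
#' strains reported in percent).
#'
#' @param param_file Parameter file from [export_spline_parameters()].
#' @param frame Frame index; default the last frame.
#' @param reference Reference frame index; default 1.
#' @param out_prefix Output path prefix.
#' @return Invisibly, the summary data frame.
#' @export
generate_strain_maps <- function(param_file, frame = NULL, reference = 1,
                                 out_prefix = "strain") {
  par <- import_spline_parameters(param_file)
  NF <- par$meta$NF
  if (is.null(frame)) frame <- NF
  field <- relative_shift_field(par$model, frame, reference,
                                nx = par$meta$nx, ny = par$meta$ny)
  maps <- equivalent_strains(deformation_tensors(field))
  px <- par$meta$pixel_size
  write_mrc(field$ux, paste0(out_prefix, "_ux.mrc"), px)
  write_mrc(field$uy, paste0(out_prefix, "_uy.mrc"), px)
  write_mrc(maps$total_eq, paste0(out_prefix, "_total_eq.mrc"), px)
  write_mrc(maps$vm_eq, paste0(out_prefix, "_vm_eq.mrc"), px)
  summary <- data.frame(
    map = c("ux_px", "uy_px", "total_eq_pct", "vm_eq_pct"),
    max = c(max(field$ux), max(field$uy),
            100 * max(maps$total_eq), 100 * max(maps$vm_eq)),
    mean = c(mean(field$ux), mean(field$uy),
             100 * mean(maps$total_eq), 100 * mean(maps$vm_eq)))
  utils::write.table(summary, paste0(out_prefix, "_summary.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}
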