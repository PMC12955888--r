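# vacuum permittivity, F/m
.EPS0 <- 8.8541878128e-12

#' Bulk material electrical properties
#'
#' A conducting dielectric with complex conductivity
#' \eqn{\sigma^*(\omega) = \sigma + j\omega\varepsilon_0\varepsilon_r}.
#'
#' @param sigma conductivity, S/m (>= 0).
#' @param eps_r relative permittivity (>= 1).
#' @param label optional material name.
#' @return an object of class \code{material_spec}.
#' @export
material_spec <- function(sigma, eps_r, label = NA_character_) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!is.finite(eps_r) || eps_r < 1) stop("eps_r must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, eps_r = eps_r, label = label),
            class = "material_spec")
}

#' Complex conductivity of a material at a frequency
#'
#' @param material a [material_spec()].
#' @param f frequency, Hz (vectorized).
#' @return complex \eqn{\sigma^* = \sigma + j\omega\varepsilon_0\varepsilon_r},
#'   S/m.
#' @export
complex_conductivity <- function(material, f) {
  stopifnot(inherits(material, "material_spec"))
  material$sigma + 1i * 2 * pi * f * .EPS0 * material$eps_r
}

#' Thin-layer (surface-impedance) specification
#'
#' Represents a thin film as an interface admittance per unit area,
#' \eqn{Y_s(\omega) = (\sigma_s + j\omega\varepsilon_0\varepsilon_{rs})/d_s}
#' (S/m^2), relating normal current density to the potential jump across the
#' film, so the film never has to be meshed.
#'
#' @param sigma_s film conductivity, S/m (>= 0).
#' @param eps_rs film relative permittivity (>= 1).
#' @param d_s film thickness, m (> 0).
#' @param label optional name.
#' @return an object of class \code{thin_layer_spec}.
#' @export
thin_layer_spec <- function(sigma_s, eps_rs, d_s, label = NA_character_) {
  if (!is.finite(d_s) || d_s <= 0) stop("d_s must be > 0", call. = FALSE)
  if (!is.finite(sigma_s) || sigma_s < 0) stop("sigma_s must be >= 0", call. = FALSE)
  if (!is.finite(eps_rs) || eps_rs < 1) stop("eps_rs must be >= 1", call. = FALSE)
  structure(list(sigma_s = sigma_s, eps_rs = eps_rs, d_s = d_s, label = label),
            class = "thin_layer_spec")
}

#' Cell-barrier surface-impedance specification
#'
#' A cell monolayer characterized by its areal (TEER-style) resistance and
#' areal capacitance; the equivalent interface admittance is
#' \eqn{Y_s(\omega) = 1/R_{areal} + j\omega C_{areal}} in SI units per m^2.
#' The cm^2-to-m^2 conversion (1 ohm cm^2 = 1e-4 ohm m^2; 1 uF/cm^2 =
#' 1e-2 F/m^2) is applied exactly once, here.
#'
#' @param r_areal_ohm_cm2 areal resistance, ohm cm^2 (> 0).
#' @param c_areal_uF_cm2 areal capacitance, uF/cm^2 (default 1, the standard
#'   membrane-capacitance scale used when only TEER is known).
#' @param label optional name (e.g. \code{"epithelial"}).
#' @return an object of class \code{barrier_spec} carrying SI fields
#'   \code{r_si} (ohm m^2) and \code{c_si} (F/m^2).
#' @export
barrier_spec <- function(r_areal_ohm_cm2, c_areal_uF_cm2 = 1,
                         label = NA_character_) {
  if (!is.finite(r_areal_ohm_cm2) || r_areal_ohm_cm2 <= 0)
    stop("areal resistance must be > 0", call. = FALSE)
  if (!is.finite(c_areal_uF_cm2) || c_areal_uF_cm2 < 0)
    stop("areal capacitance must be >= 0", call. = FALSE)
  structure(list(r_areal_ohm_cm2 = r_areal_ohm_cm2,
                 c_areal_uF_cm2 = c_areal_uF_cm2,
                 r_si = r_areal_ohm_cm2 * 1e-4,
                 c_si = c_areal_uF_cm2 * 1e-2,
                 label = label),
            class = "barrier_spec")
}

#' Interface admittance per unit area at a frequency
#'
#' @param x a [thin_layer_spec()], [barrier_spec()], or a list of them (stacked
#'   films on one interface combine in series).
#' @param f frequency, Hz.
#' @return complex admittance per area, S/m^2.
#' @export
admittance_per_area <- function(x, f) UseMethod("admittance_per_area")

#' @export
admittance_per_area.thin_layer_spec <- function(x, f) {
  ys <- (x$sigma_s + 1i * 2 * pi * f * .EPS0 * x$eps_rs) / x$d_s
  if (any(!is.finite(Mod(ys))) || any(Mod(ys) == 0))
    stop("thin layer admittance must be finite and nonzero at all frequencies",
         call. = FALSE)
  ys
}

#' @export
admittance_per_area.barrier_spec <- function(x, f) {
  1 / x$r_si + 1i * 2 * pi * f * x$c_si
}

#' @export
admittance_per_area.list <- function(x, f) {
  stopifnot(length(x) >= 1L)
  inv <- 0
  for (layer in x) inv <- inv + 1 / admittance_per_area(layer, f)
  1 / inv
}

#' PEDOT:PSS electrode-coating thin layer
#'
#' The conducting-polymer coating is represented as a surface impedance behind
#' each equipotential electrode terminal. Its constants are a documented
#' placeholder emulating a low-impedance pseudo-capacitive coating (areal
#' capacitance default 20 mF/cm^2 = 200 F/m^2, negligible DC leakage): the
#' film's true constants are device-fabrication specific and are config values
#' here.
#'
#' @param c_areal_f_m2 areal capacitance, F/m^2 (default 200).
#' @param sigma_s film DC conductivity, S/m (default 0: purely capacitive
#'   coupling).
#' @param d_s film thickness, m (default 400 nm).
#' @return a [thin_layer_spec()].
#' @export
pedot_layer <- function(c_areal_f_m2 = 200, sigma_s = 0, d_s = 4e-7) {
  thin_layer_spec(sigma_s = sigma_s, eps_rs = c_areal_f_m2 * d_s / .EPS0,
                  d_s = d_s, label = "PEDOT:PSS")
}

#' Device model: 2D layered cross-section with terminals and interfaces
#'
#' Low-level constructor; most users call [build_device()] or
#' [build_slab_device()]. The rectangle is tiled top-to-bottom by bands of
#' bulk material; barriers and films sit on internal horizontal interfaces
#' (with duplicated mesh nodes and a jump condition); electrodes are
#' equipotential boundary segments, either behind a contact-impedance thin
#' layer (\code{type = "robin"}) or as strong Dirichlet constraints
#' (\code{type = "dirichlet"}).
#'
#' @param bands list of \code{list(name, thickness, material)} from the top
#'   (device face) downward; thicknesses in m.
#' @param interfaces list of \code{list(label, y, layers)} where \code{y} is an
#'   internal band boundary depth and \code{layers} a list of
#'   [thin_layer_spec()]/[barrier_spec()] stacked in series.
#' @param electrodes named list of \code{list(boundary, x, potential, type,
#'   layer)}: boundary \code{"top"} or \code{"bottom"}, \code{x = c(x0, x1)}
#'   the segment span in m, \code{potential} the applied terminal potential in
#'   V, \code{type} \code{"robin"} or \code{"dirichlet"}, \code{layer} the
#'   contact thin layer for robin terminals.
#' @param width domain width, m.
#' @param depth out-of-plane depth, m (converts 2D current density to A).
#' @param scenario optional scenario label.
#' @param material_fn optional override: function \code{(x, y, f)} returning
#'   the complex conductivity at element centroids (used for manufactured
#'   solutions in convergence studies).
#' @return an object of class \code{device_model}.
#' @export
device_model <- function(bands, interfaces = list(), electrodes, width, depth,
                         scenario = NA_character_, material_fn = NULL) {
  stopifnot(length(bands) >= 1L, length(electrodes) >= 2L,
            width > 0, depth > 0)
  th <- vapply(bands, function(b) b$thickness, numeric(1))
  if (any(th <= 0)) stop("band thicknesses must be > 0", call. = FALSE)
  ybreaks <- cumsum(c(0, th))
  height <- ybreaks[length(ybreaks)]
  for (ifc in interfaces) {
    hit <- which(abs(ybreaks - ifc$y) <= 1e-12 * max(height, 1))
    if (length(hit) != 1L || hit == 1L || hit == length(ybreaks))
      stop(sprintf("interface '%s' at y = %g must lie on an internal band boundary",
                   ifc$label, ifc$y), call. = FALSE)
  }
  spans <- t(vapply(electrodes, function(e) e$x, numeric(2)))
  for (e in electrodes) {
    if (e$x[1] < -1e-15 || e$x[2] > width + 1e-15 || e$x[2] <= e$x[1])
      stop("electrode segment outside the domain or empty", call. = FALSE)
    if (!e$boundary %in% c("top", "bottom"))
      stop("electrode boundary must be 'top' or 'bottom'", call. = FALSE)
    if (!e$type %in% c("robin", "dirichlet"))
      stop("electrode type must be 'robin' or 'dirichlet'", call. = FALSE)
  }
  same_side <- split(seq_along(electrodes),
                     vapply(electrodes, function(e) e$boundary, character(1)))
  for (idx in same_side) {
    if (length(idx) < 2L) next
    sp <- spans[idx, , drop = FALSE]
    sp <- sp[order(sp[, 1]), , drop = FALSE]
    if (any(sp[-1, 1] < sp[-nrow(sp), 2] - 1e-15))
      stop("electrode segments on one boundary must be disjoint", call. = FALSE)
  }
  structure(list(bands = bands, interfaces = interfaces,
                 electrodes = electrodes, width = width, height = height,
                 ybreaks = ybreaks, depth = depth, scenario = scenario,
                 material_fn = material_fn),
            class = "device_model")
}

#' @export
print.device_model <- function(x, ...) {
  cat(sprintf("device model '%s': %.3g x %.3g mm cross-section, depth %.3g mm\n",
              x$scenario, x$width * 1e3, x$height * 1e3, x$depth * 1e3))
  for (b in x$bands)
    cat(sprintf("  band %-14s %8.3g mm  (sigma = %.3g S/m, eps_r = %g)\n",
                b$name, b$thickness * 1e3, b$material$sigma, b$material$eps_r))
  for (ifc in x$interfaces)
    cat(sprintf("  interface '%s' at depth %.3g mm (%d layer(s))\n",
                ifc$label, ifc$y * 1e3, length(ifc$layers)))
  for (nm in names(x$electrodes)) {
    e <- x$electrodes[[nm]]
    cat(sprintf("  electrode %-4s on %s boundary, x = [%.3g, %.3g] mm, %s, %g V\n",
                nm, e$boundary, e$x[1] * 1e3, e$x[2] * 1e3, e$type, e$potential))
  }
  invisible(x)
}

#' Build the conformable-device / multi-barrier culture cross-section
#'
#' Canonical scenarios of the simulation study. The device (working electrode
#' WE, 400 um wide, and counter/reference electrode CE, 1 mm wide, 1.5 mm
#' edge-to-edge apart, both behind a PEDOT:PSS contact layer) sits on the top
#' boundary. Because the measurement protocol removes the apical media so the
#' device rests directly on the tissue, only a thin residual fluid film
#' (default 20 um) separates the electrodes from the first barrier; below it
#' follow, depending on scenario, the matrix-laden hydrogel (3 mm), the porous
#' insert membrane (thin layer), the second barrier, and bulk medium.
#' \describe{
#'   \item{blank}{culture medium only, no barriers.}
#'   \item{huvec_only}{a single endothelial monolayer on the insert membrane.}
#'   \item{quad_apical}{device on the epithelial face: epithelial barrier near
#'     the electrodes, hydrogel, then membrane + endothelial barrier far away.}
#'   \item{quad_basal}{device on the inverted insert's endothelial face:
#'     membrane + endothelial barrier near, hydrogel, epithelial barrier far.}
#' }
#' Barrier areal resistances default to the synthetic population's epithelial
#' and endothelial R2 medians divided by the geometric effective measurement
#' area, so simulated sweeps and generator spectra live on the same scale.
#'
#' @param scenario one of \code{"blank"}, \code{"huvec_only"},
#'   \code{"quad_apical"}, \code{"quad_basal"}.
#' @param config named list of overrides: geometry (\code{width_m},
#'   \code{height_m}, \code{depth_m}, \code{we_width_m}, \code{ce_width_m},
#'   \code{gap_m}, \code{film_m}, \code{gel_m}), materials (\code{medium},
#'   \code{gel} as [material_spec()]), films (\code{pedot}, \code{membrane} as
#'   [thin_layer_spec()]), barriers (\code{epithelial}, \code{endothelial} as
#'   [barrier_spec()]), \code{v_applied}, \code{population} (a
#'   [population_spec()] used for the barrier defaults).
#' @return a [device_model()].
#' @export
build_device <- function(scenario = c("blank", "huvec_only", "quad_apical",
                                      "quad_basal"),
                         config = list()) {
  scenario <- match.arg(scenario)
  cfg <- utils::modifyList(list(
    width_m = 4e-3, height_m = 4.5e-3, depth_m = 4e-4,
    we_width_m = 4e-4, ce_width_m = 1e-3, gap_m = 1.5e-3,
    film_m = 2e-5, gel_m = 3e-3,
    medium = material_spec(1.5, 80, "culture medium"),
    gel = material_spec(0.05, 100, "matrix-laden hydrogel"),
    pedot = pedot_layer(),
    membrane = NULL, membrane_porosity = 0.1, membrane_d_m = 1e-5,
    epithelial = NULL, endothelial = NULL,
    c_areal_uF_cm2 = 1, population = population_spec(),
    v_applied = 0.01), config)

  if (is.null(cfg$membrane))
    cfg$membrane <- thin_layer_spec(
      sigma_s = cfg$medium$sigma * cfg$membrane_porosity, eps_rs = 3,
      d_s = cfg$membrane_d_m, label = "porous PET membrane")

  a_eff_cm2 <- 1e4 * .effective_area(cfg)   # m^2 -> cm^2
  if (is.null(cfg$epithelial))
    cfg$epithelial <- barrier_spec(
      cfg$population$epithelial$R2_median * a_eff_cm2,
      cfg$c_areal_uF_cm2, "epithelial")
  if (is.null(cfg$endothelial))
    cfg$endothelial <- barrier_spec(
      cfg$population$endothelial$R2_median * a_eff_cm2,
      cfg$c_areal_uF_cm2, "endothelial")

  margin <- (cfg$width_m - cfg$we_width_m - cfg$gap_m - cfg$ce_width_m) / 2
  if (margin <= 0) stop("electrodes do not fit in the domain width", call. = FALSE)
  we_x <- c(margin, margin + cfg$we_width_m)
  ce_x <- c(margin + cfg$we_width_m + cfg$gap_m,
            margin + cfg$we_width_m + cfg$gap_m + cfg$ce_width_m)
  electrodes <- list(
    we = list(boundary = "top", x = we_x, potential = cfg$v_applied,
              type = "robin", layer = cfg$pedot),
    ce = list(boundary = "top", x = ce_x, potential = 0,
              type = "robin", layer = cfg$pedot))

  film <- list(name = "residual film", thickness = cfg$film_m,
               material = cfg$medium)
  gel <- list(name = "hydrogel", thickness = cfg$gel_m, material = cfg$gel)
  rest_m <- cfg$height_m - cfg$film_m
  rest_q <- cfg$height_m - cfg$film_m - cfg$gel_m
  if (rest_q <= 0) stop("domain height too small for the layer stack", call. = FALSE)
  medium_band <- function(t) list(name = "medium", thickness = t,
                                  material = cfg$medium)

  geom <- switch(scenario,
    blank = list(
      bands = list(medium_band(cfg$height_m)),
      interfaces = list()),
    huvec_only = list(
      bands = list(film, medium_band(rest_m)),
      interfaces = list(list(label = "endothelial", y = cfg$film_m,
                             layers = list(cfg$endothelial, cfg$membrane)))),
    quad_apical = list(
      bands = list(film, gel, medium_band(rest_q)),
      interfaces = list(
        list(label = "epithelial", y = cfg$film_m,
             layers = list(cfg$epithelial)),
        list(label = "endothelial", y = cfg$film_m + cfg$gel_m,
             layers = list(cfg$membrane, cfg$endothelial)))),
    quad_basal = list(
      bands = list(film, gel, medium_band(rest_q)),
      interfaces = list(
        list(label = "endothelial", y = cfg$film_m,
             layers = list(cfg$endothelial, cfg$membrane)),
        list(label = "epithelial", y = cfg$film_m + cfg$gel_m,
             layers = list(cfg$epithelial)))))

  device_model(bands = geom$bands, interfaces = geom$interfaces,
               electrodes = electrodes, width = cfg$width_m,
               depth = cfg$depth_m, scenario = scenario)
}

# effective measurement area (m^2): series combination of the WE and CE
# footprints, each widened by one film thickness of lateral spreading per edge
.effective_area <- function(cfg) {
  a_we <- cfg$depth_m * (cfg$we_width_m + 2 * cfg$film_m)
  a_ce <- cfg$depth_m * (cfg$ce_width_m + 2 * cfg$film_m)
  1 / (1 / a_we + 1 / a_ce)
}

#' Effective measurement area of the device
#'
#' The current crosses the near barrier twice (down under the WE, back up under
#' the CE), so the electrode-scale barrier resistance is
#' \eqn{R_2 = \rho_s (1/A_{WE} + 1/A_{CE})} with footprints widened by lateral
#' spreading of about one film thickness per edge. This function returns the
#' series-combined area \eqn{A_{eff} = (1/A_{WE} + 1/A_{CE})^{-1}} implied by
#' the model geometry, in m^2: the conversion factor between a barrier's areal
#' resistance (ohm m^2) and the R2 a spectrum fit recovers (ohm).
#'
#' @param model a [device_model()] built by [build_device()].
#' @param film_m residual-film thickness used as the spreading margin
#'   (defaults to the model's first-band thickness).
#' @return effective area, m^2.
#' @export
effective_measurement_area <- function(model, film_m = NULL) {
  stopifnot(inherits(model, "device_model"))
  if (is.null(film_m)) film_m <- model$bands[[1]]$thickness
  widths <- vapply(model$electrodes, function(e) diff(e$x), numeric(1))
  a <- model$depth * (widths + 2 * film_m)
  1 / sum(1 / a)
}

#' Build a layered parallel-plate (1D limit) device
#'
#' Full-width plate terminals on the top and bottom boundaries enclosing a
#' stack of material layers and optional interface films: the geometry whose
#' impedance has the closed form \eqn{Z = \sum_k d_k/(\sigma^*_k A) +
#' \sum_m 1/(Y_{s,m} A)}, used as the validation oracle for the solver.
#'
#' @param layers list of \code{list(material, thickness)} from top to bottom.
#' @param thin_layers list of \code{list(y, layers)} interface films at
#'   internal layer boundaries (depth y in m).
#' @param width,depth plate width and out-of-plane depth, m (plate area =
#'   width x depth).
#' @param v_applied potential applied at the top plate, V.
#' @param terminal_layers optional list \code{list(top =, bottom =)} of
#'   [thin_layer_spec()] contact films; plates without one are strong Dirichlet
#'   terminals.
#' @param material_fn optional centroid-wise conductivity override, see
#'   [device_model()].
#' @return a [device_model()].
#' @export
build_slab_device <- function(layers, thin_layers = list(), width = 1e-3,
                              depth = 1e-3, v_applied = 0.01,
                              terminal_layers = list(), material_fn = NULL) {
  bands <- lapply(seq_along(layers), function(k)
    list(name = paste0("layer", k), thickness = layers[[k]]$thickness,
         material = layers[[k]]$material))
  mk_term <- function(side, pot) {
    lay <- terminal_layers[[side]]
    list(boundary = side, x = c(0, width), potential = pot,
         type = if (is.null(lay)) "dirichlet" else "robin", layer = lay)
  }
  device_model(bands = bands, interfaces = thin_layers,
               electrodes = list(we = mk_term("top", v_applied),
                                 ce = mk_term("bottom", 0)),
               width = width, depth = depth, scenario = "slab",
               material_fn = material_fn)
}

#' Analytic impedance of a layered slab
#'
#' Closed-form series impedance of a 1D stack of bulk layers and interface
#' films across a plate of the given area:
#' \deqn{Z(f) = \sum_k \frac{d_k}{\sigma^*_k(f)\,A} +
#'   \sum_m \frac{1}{Y_{s,m}(f)\,A}.}
#'
#' @param layers list of \code{list(material, thickness)}.
#' @param thin_layers list of [thin_layer_spec()]/[barrier_spec()] (positions
#'   are irrelevant for the series formula).
#' @param area plate area, m^2 (> 0).
#' @param f frequency, Hz (vectorized).
#' @return complex impedance, ohm.
#' @export
analytic_layered_slab <- function(layers, thin_layers = list(), area, f) {
  if (length(layers) < 1L) stop("need >= 1 layer", call. = FALSE)
  if (!is.numeric(area) || area <= 0) stop("area must be > 0", call. = FALSE)
  z <- rep(0 + 0i, length(f))
  for (lay in layers)
    z <- z + lay$thickness / (complex_conductivity(lay$material, f) * area)
  for (tl in thin_layers)
    z <- z + 1 / (admittance_per_area(tl, f) * area)
  z
}
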