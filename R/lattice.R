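#' Tube lattice parameters
#'
#' Bundles the geometric parameters of an N-protofilament helical tube:
#' the number of straight protofilaments, the lateral (center-to-center)
#' spacing between adjacent protofilament axes, the axial stagger between
#' neighbours, the subunit rises along a protofilament, the protofilament
#' thickness, and the lateral packing rule (A- or B-lattice). Defaults are
#' the published BtubA/B model-building values: 4.6 nm lateral spacing,
#' 0.88 nm stagger, 8.8 nm heterodimer repeat (4.4 nm monomer rise) and
#' 4.0 nm protofilament diameter; the eukaryotic reference stagger is
#' 0.93 nm.
#'
#' @param n_pf integer number of protofilaments (>= 1).
#' @param lateral_spacing_nm chord distance between adjacent protofilament
#'   axes, measured in the plane perpendicular to the tube axis.
#' @param axial_stagger_nm axial shift between adjacent protofilaments.
#' @param dimer_rise_nm heterodimer repeat along one protofilament.
#' @param monomer_rise_nm axial repeat of one monomer; must equal
#'   `dimer_rise_nm / 2`.
#' @param pf_diameter_nm protofilament thickness.
#' @param lattice_type `"A"` (lateral neighbours of unlike type) or `"B"`
#'   (lateral neighbours of like type; closure then forces a seam).
#' @param tube_length_nm requested model length.
#' @return an object of class `tube_spec`.
#' @export
tube_lattice_spec <- function(n_pf = 5,
                              lateral_spacing_nm = 4.6,
                              axial_stagger_nm = 0.88,
                              dimer_rise_nm = 8.8,
                              monomer_rise_nm = dimer_rise_nm / 2,
                              pf_diameter_nm = 4.0,
                              lattice_type = c("B", "A"),
                              tube_length_nm = 52.8) {
  lattice_type <- match.arg(lattice_type)
  n_pf <- as.integer(n_pf)
  stopifnot(n_pf >= 1L)
  lens <- c(lateral_spacing_nm, axial_stagger_nm, dimer_rise_nm,
            monomer_rise_nm, pf_diameter_nm, tube_length_nm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lattice lengths must be positive and finite")
  if (abs(monomer_rise_nm - dimer_rise_nm / 2) > 1e-9)
    stop("monomer_rise_nm must equal dimer_rise_nm / 2")
  structure(list(n_pf = n_pf,
                 lateral_spacing_nm = lateral_spacing_nm,
                 axial_stagger_nm = axial_stagger_nm,
                 dimer_rise_nm = dimer_rise_nm,
                 monomer_rise_nm = monomer_rise_nm,
                 pf_diameter_nm = pf_diameter_nm,
                 lattice_type = lattice_type,
                 tube_length_nm = tube_length_nm),
            class = "tube_spec")
}

#' @export
print.tube_spec <- function(x, ...) {
  cat(sprintf("tube lattice: %d protofilaments, %s-lattice\n", x$n_pf, x$lattice_type))
  cat(sprintf("  lateral spacing %.2f nm, stagger %.2f nm, monomer rise %.2f nm\n",
              x$lateral_spacing_nm, x$axial_stagger_nm, x$monomer_rise_nm))
  cat(sprintf("  requested length %.1f nm\n", x$tube_length_nm))
  invisible(x)
}

#' Circumradius of the protofilament ring
#'
#' Radius of the circle on which `n_pf` protofilament axes sit so that
#' adjacent axes are separated by a chord of `lateral_spacing_nm`:
#' `r = s / (2 sin(pi/N))`. Twice this value is the center-to-center tube
#' diameter (7.8 nm for five protofilaments at 4.6 nm spacing, 9.2 nm for
#' six).
#'
#' @param n_pf number of protofilaments (>= 2).
#' @param lateral_spacing_nm chord between adjacent axes.
#' @return ring radius in nm.
#' @export
ring_radius <- function(n_pf, lateral_spacing_nm) {
  if (n_pf < 2) stop("ring geometry needs at least 2 protofilaments")
  if (lateral_spacing_nm <= 0) stop("lateral spacing must be positive")
  lateral_spacing_nm / (2 * sin(pi / n_pf))
}

#' Per-protofilament stagger of a one-start tube with a given closure repeat
#'
#' Inverts the one-start closure relation: if going once around the tube
#' (N lateral steps) must climb exactly `repeat_nm`, each step climbs
#' `repeat_nm / n_pf`. A 4.65 nm closure over five protofilaments gives the
#' eukaryotic 0.93 nm stagger; 4.4 and 4.2 nm give 0.88 and 0.84 nm.
#'
#' @param repeat_nm closure (helical) repeat.
#' @param n_pf number of protofilaments.
#' @return stagger in nm.
#' @export
stagger_for_repeat <- function(repeat_nm, n_pf) {
  stopifnot(repeat_nm > 0, n_pf >= 1)
  repeat_nm / n_pf
}

#' Helix start number of a lattice spec
#'
#' Number of independent helical strands: the closure climb `N * stagger`
#' measured in monomer rises, rounded half away from zero. One for the
#' five-protofilament BtubA/B lattice; three for the eukaryotic
#' 13-protofilament microtubule (13 x 0.93 / 4.03).
#'
#' @param spec a [tube_lattice_spec()].
#' @return integer start number.
#' @export
start_number <- function(spec) {
  x <- spec$n_pf * spec$axial_stagger_nm / spec$monomer_rise_nm
  if (abs(abs(x - floor(x)) - 0.5) < 1e-9)
    warning("closure climb is exactly half a monomer rise; start number is degenerate")
  as.integer(round_half_away(x))
}

#' Geometric report for a tube lattice
#'
#' Center-to-center and outer-envelope diameters, helix start number,
#' closure repeat and seam count for a lattice spec. The diameter
#' convention is twice the circumradius of the protofilament axes (this is
#' the convention that reproduces the published 7.8 and 9.2 nm values);
#' the outer envelope adds one protofilament thickness.
#'
#' @param spec a [tube_lattice_spec()].
#' @return a `lattice_report` list with fields `diameter_nm`,
#'   `outer_diameter_nm`, `start_number`, `closure_repeat_nm`, `seam_count`.
#' @export
derive_lattice_report <- function(spec) {
  r <- if (spec$n_pf >= 2) ring_radius(spec$n_pf, spec$lateral_spacing_nm) else 0
  sn <- start_number(spec)
  model <- assign_subunit_types(build_tube(spec), spec$lattice_type)
  structure(list(diameter_nm = 2 * r,
                 outer_diameter_nm = 2 * r + spec$pf_diameter_nm,
                 start_number = sn,
                 closure_repeat_nm = spec$n_pf * spec$axial_stagger_nm,
                 seam_count = nrow(model$seam_junctions)),
            class = "lattice_report")
}

#' @export
print.lattice_report <- function(x, ...) {
  cat(sprintf("diameter %.1f nm (outer %.1f nm), %d-start, closure repeat %.2f nm, %d seam(s)\n",
              x$diameter_nm, x$outer_diameter_nm, x$start_number,
              x$closure_repeat_nm, x$seam_count))
  invisible(x)
}

#' Build a finite tube model from a lattice spec
#'
#' Places one pseudo-subunit per monomer. Protofilament `j` (0-based) sits
#' at azimuth `2*pi*j/N` on the ring of [ring_radius()], axially offset by
#' `j * stagger`; subunits stack at `monomer_rise_nm` intervals along +z
#' (the tube axis), and the whole model is centered on the origin.
#' Protofilaments are straight and parallel to the axis unless a
#' `twist_deg_per_nm` supertwist is requested (a control used to test the
#' straightness analysis, not a published geometry).
#'
#' @param spec a [tube_lattice_spec()].
#' @param twist_deg_per_nm protofilament supertwist about the tube axis,
#'   degrees of azimuth per nm of height; 0 (default) gives straight
#'   protofilaments.
#' @return a `tube_model`: spec, `placements` data frame (`pf`, `axial`,
#'   `type`, `x`, `y`, `z` in nm), `ring_radius_nm`, `seam_junctions`,
#'   and the lab-frame axis direction (+z until [orient_model()] is used).
#' @export
build_tube <- function(spec, twist_deg_per_nm = 0) {
  stopifnot(inherits(spec, "tube_spec"))
  if (spec$tube_length_nm < 2 * spec$monomer_rise_nm)
    stop("tube_length_nm must cover at least two monomer rises")
  r <- if (spec$n_pf >= 2) ring_radius(spec$n_pf, spec$lateral_spacing_nm) else 0
  n_axial <- max(2L, as.integer(floor(spec$tube_length_nm / spec$monomer_rise_nm + 1e-9)))
  pf <- rep(seq_len(spec$n_pf) - 1L, each = n_axial)
  axial <- rep(seq_len(n_axial) - 1L, times = spec$n_pf)
  z <- axial * spec$monomer_rise_nm + pf * spec$axial_stagger_nm
  z <- z - mean(range(z))
  phi <- 2 * pi * pf / spec$n_pf + deg2rad(twist_deg_per_nm) * z
  placements <- data.frame(pf = pf, axial = axial,
                           type = NA_character_,
                           x = r * cos(phi), y = r * sin(phi), z = z)
  model <- structure(list(spec = spec,
                          placements = placements,
                          ring_radius_nm = r,
                          seam_junctions = empty_junctions(),
                          twist_deg_per_nm = twist_deg_per_nm,
                          axis_lab = c(0, 0, 1)),
                     class = "tube_model")
  assign_subunit_types(model, spec$lattice_type)
}

empty_junctions <- function() {
  data.frame(pf_a = integer(0), pf_b = integer(0), contact = character(0))
}

#' @export
print.tube_model <- function(x, ...) {
  cat(sprintf("tube model: %d protofilaments x %d monomers (%d placements), ring radius %.3f nm\n",
              x$spec$n_pf, nrow(x$placements) / x$spec$n_pf,
              nrow(x$placements), x$ring_radius_nm))
  if (x$twist_deg_per_nm != 0)
    cat(sprintf("  supertwist %.2f deg/nm\n", x$twist_deg_per_nm))
  cat(sprintf("  lattice type %s, %d seam junction(s)\n",
              x$spec$lattice_type, nrow(x$seam_junctions)))
  invisible(x)
}

## For each adjacent protofilament pair (j, j+1 mod N), find the lateral
## partner of each subunit of pf j by nearest axial position in pf j+1.
## Returns one row per contacting subunit pair.
enumerate_lateral_contacts <- function(model) {
  sp <- model$spec
  if (sp$n_pf < 2) {
    return(data.frame(pf_a = integer(0), pf_b = integer(0),
                      axial_a = integer(0), axial_b = integer(0),
                      dist_nm = numeric(0)))
  }
  pl <- model$placements
  out <- vector("list", sp$n_pf)
  for (j in seq_len(sp$n_pf) - 1L) {
    k <- (j + 1L) %% sp$n_pf
    a <- pl[pl$pf == j, ]
    b <- pl[pl$pf == k, ]
    ## nearest-z partner in pf k for every subunit of pf j
    idx <- vapply(a$z, function(z0) which.min(abs(b$z - z0)), integer(1))
    d <- sqrt((a$x - b$x[idx])^2 + (a$y - b$y[idx])^2 + (a$z - b$z[idx])^2)
    out[[j + 1L]] <- data.frame(pf_a = a$pf, pf_b = b$pf[idx],
                                axial_a = a$axial, axial_b = b$axial[idx],
                                dist_nm = d)
  }
  do.call(rbind, out)
}

#' Assign A/B subunit identities and locate the seam
#'
#' Monomers alternate A, B along each protofilament (one heterodimer every
#' two monomers). In a B-lattice laterally adjacent subunits at matching
#' axial levels carry the same identity, so the alternation phase is shared
#' by all protofilaments; in an A-lattice neighbours alternate, so the
#' phase flips from one protofilament to the next. Lateral contacts are
#' then enumerated by brute force (nearest axial partner in the next
#' protofilament) and every contact violating the lattice rule is recorded
#' as a seam junction. For the one-start five-protofilament tube the
#' B-lattice closes with exactly one seam and the A-lattice closes without
#' one.
#'
#' @param model a `tube_model`.
#' @param lattice_type `"A"` or `"B"`; defaults to the spec's.
#' @return the model with `placements$type` filled in and
#'   `seam_junctions` populated.
#' @export
assign_subunit_types <- function(model, lattice_type = model$spec$lattice_type) {
  stopifnot(inherits(model, "tube_model"))
  lattice_type <- match.arg(lattice_type, c("A", "B"))
  pl <- model$placements
  phase <- if (lattice_type == "B") pl$axial %% 2L else (pl$axial + pl$pf) %% 2L
  pl$type <- ifelse(phase == 0L, "A", "B")
  model$placements <- pl
  contacts <- enumerate_lateral_contacts(model)
  if (nrow(contacts) == 0) {
    model$seam_junctions <- empty_junctions()
    return(model)
  }
  type_of <- function(pf, axial) {
    ph <- if (lattice_type == "B") axial %% 2L else (axial + pf) %% 2L
    ifelse(ph == 0L, "A", "B")
  }
  contacts$homotypic <- type_of(contacts$pf_a, contacts$axial_a) ==
    type_of(contacts$pf_b, contacts$axial_b)
  ## per junction (pf pair), the dominant contact class; a seam is a
  ## junction whose contacts violate the lattice rule
  agg <- aggregate(homotypic ~ pf_a + pf_b, data = contacts,
                   FUN = function(h) mean(h) > 0.5)
  rule_homotypic <- lattice_type == "B"
  seams <- agg[agg$homotypic != rule_homotypic, c("pf_a", "pf_b")]
  seams$contact <- rep(if (rule_homotypic) "heterotypic" else "homotypic",
                       nrow(seams))
  rownames(seams) <- NULL
  model$seam_junctions <- seams
  model
}

#' Lateral-contact feasibility report
#'
#' For each adjacent protofilament pair, the minimal 3-D center-to-center
#' subunit distance and whether it is within `max_center_gap_nm`. This is
#' the check behind rejecting the eukaryotic 5 nm spacing for these small
#' tubes: at 5 nm the lateral gap exceeds what protofilament interactions
#' can bridge, while 4.6 nm keeps all junctions feasible.
#'
#' @param model a `tube_model`.
#' @param max_center_gap_nm feasibility threshold on the 3-D center
#'   distance (default 4.8).
#' @return data frame: `pf_a`, `pf_b`, `min_dist_nm`, `feasible`.
#' @export
check_lateral_contacts <- function(model, max_center_gap_nm = 4.8) {
  contacts <- enumerate_lateral_contacts(model)
  if (nrow(contacts) == 0) {
    return(data.frame(pf_a = integer(0), pf_b = integer(0),
                      min_dist_nm = numeric(0), feasible = logical(0)))
  }
  agg <- aggregate(dist_nm ~ pf_a + pf_b, data = contacts, FUN = min)
  names(agg)[3] <- "min_dist_nm"
  agg$feasible <- agg$min_dist_nm <= max_center_gap_nm
  agg[order(agg$pf_a), , drop = FALSE]
}
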