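#' Per-zone liquid (plasma) fraction
#'
#' `sum(alpha * cell volume) / zone volume` for each analysis zone; this is
#' the zone-resolved plasma density of the model, in `[0, 1]`.
#'
#' @param state a `flow_state`.
#' @param geom a zoned [domain_geometry][rasterize_domain()].
#' @return Named numeric vector over `interface`, `thread`, `outer`.
#' @export
zone_liquid_fraction <- function(state, geom) {
  if (!all(dim(state$alpha) == dim(geom$zone)))
    stop("zone_liquid_fraction: state and zones have mismatched grids")
  zl <- c(interface = ZN_INTERFACE, thread = ZN_THREAD, outer = ZN_OUTER)
  vapply(zl, function(z) {
    n <- sum(geom$zone == z)
    if (n == 0) stop("zone_liquid_fraction: empty zone")
    sum(state$alpha[geom$zone == z]) / n
  }, numeric(1))
}

#' Per-zone mean velocity vectors and speed
#'
#' Liquid-weighted mean of the cell-centred velocity per zone, reported in
#' the model's sign conventions: `vertical` is the axial component,
#' positive upbound (toward the outlet); `horizontal` is the lateral
#' component along the inward surface normal, positive inbound (toward the
#' implant axis); `speed` is the magnitude of the mean vector. A secondary
#' `mean_cell_speed` (liquid-weighted mean of per-cell speeds) is also
#' returned. Zones holding no liquid are flagged `NA` (undefined, not
#' zero).
#'
#' @param state a `flow_state`.
#' @param geom a zoned [domain_geometry][rasterize_domain()].
#' @param weighted liquid-weighted means (default); `FALSE` gives
#'   unweighted cell means over the zone.
#' @return A data.frame with rows `interface`, `thread`, `outer` and
#'   columns `vertical`, `horizontal`, `speed`, `mean_cell_speed`.
#' @export
zone_mean_vectors <- function(state, geom, weighted = TRUE) {
  if (!all(dim(state$alpha) == dim(geom$zone)))
    stop("zone_mean_vectors: state and zones have mismatched grids")
  nx <- geom$nx; ny <- geom$ny
  uc <- 0.5 * (state$u[1:nx, , drop = FALSE] +
                 state$u[2:(nx + 1L), , drop = FALSE])
  vc <- 0.5 * (state$v[, 1:ny, drop = FALSE] +
                 state$v[, 2:(ny + 1L), drop = FALSE])
  w <- if (weighted) state$alpha else (geom$zone > 0) * 1
  zl <- c(interface = ZN_INTERFACE, thread = ZN_THREAD, outer = ZN_OUTER)
  res <- lapply(zl, function(z) {
    sel <- geom$zone == z
    sw <- sum(w[sel])
    if (sw < 1e-12)
      return(c(vertical = NA_real_, horizontal = NA_real_,
               speed = NA_real_, mean_cell_speed = NA_real_))
    mu <- sum(w[sel] * uc[sel]) / sw
    mv <- sum(w[sel] * vc[sel]) / sw
    msp <- sum(w[sel] * sqrt(uc[sel]^2 + vc[sel]^2)) / sw
    ## inbound = toward the implant axis = -x in the half-domain
    c(vertical = mv, horizontal = -mu, speed = sqrt(mu^2 + mv^2),
      mean_cell_speed = msp)
  })
  as.data.frame(do.call(rbind, res))
}

## Final-time rows of a zone series, one per zone.
series_at_end <- function(series) {
  tend <- max(series$time)
  series[series$time == tend, , drop = FALSE]
}

#' Blood and protein recruitment totals
#'
#' Total liquid volume and species mass infiltrated into the interface and
#' thread zones together at the final time of a zone series.
#'
#' @param series a zone time-series data.frame as produced by
#'   [run_simulation()] (columns `time`, `zone`, `zone_volume`,
#'   `liquid_fraction`, `species_mass`).
#' @return Named vector `c(blood = ..., species = ...)` (mm2).
#' @export
recruitment_totals <- function(series) {
  fin <- series_at_end(series)
  fin <- fin[fin$zone %in% c("interface", "thread"), , drop = FALSE]
  if (nrow(fin) < 2) stop("recruitment_totals: final time rows missing")
  c(blood = sum(fin$liquid_fraction * fin$zone_volume),
    species = sum(fin$species_mass))
}

#' Interfacial recruitment efficiency
#'
#' Infiltration into the interface zone as a percentage of infiltration
#' into the thread zone, at the final time, separately for blood (liquid
#' volume) and the protein.
#'
#' @param series a zone time-series data.frame (see [recruitment_totals()]).
#' @return Named vector `c(blood = ..., species = ...)` in percent.
#' @export
recruitment_efficiency <- function(series) {
  fin <- series_at_end(series)
  it <- fin[fin$zone == "interface", , drop = FALSE]
  th <- fin[fin$zone == "thread", , drop = FALSE]
  if (nrow(it) != 1 || nrow(th) != 1)
    stop("recruitment_efficiency: final time rows missing")
  bl_th <- th$liquid_fraction * th$zone_volume
  sp_th <- th$species_mass
  if (bl_th <= 0 || (sp_th <= 0 && it$species_mass > 0))
    stop("recruitment_efficiency: thread-zone quantity is zero")
  c(blood = 100 * (it$liquid_fraction * it$zone_volume) / bl_th,
    species = if (sp_th > 0) 100 * it$species_mass / sp_th else NA_real_)
}

## Qualitative label from a ratio-to-baseline (density/quantity sense).
ratio_label <- function(r, hi = 1.5, lo = 1.15) {
  if (!is.finite(r)) return(NA_character_)
  if (r >= hi) "++" else if (r >= lo) "+" else if (r <= 1 / lo) "-"
  else "+/-"
}

## Speed labels carry the inverted sense: slower than baseline is notable.
speed_label <- function(r, hi = 1.5, lo = 1.15) {
  if (!is.finite(r)) return(NA_character_)
  if (r <= 1 / hi) "Very slow" else if (r <= 1 / lo) "Slow"
  else if (r >= lo) "Fast" else "+/-"
}

direction_label <- function(vertical, horizontal) {
  if (!is.finite(vertical) || !is.finite(horizontal)) return(NA_character_)
  paste(if (vertical >= 0) "Up" else "Down",
        "and", if (horizontal >= 0) "In" else "Out")
}

#' Compare topographies
#'
#' Builds the cross-topography summary: per-topography and per-zone
#' densities, speeds, vector direction words, species masses at the final
#' time; recruitment totals and interfacial recruitment efficiencies;
#' pairwise fold ratios; and qualitative labels relative to the
#' `"amorphous"` baseline (`++` at a fold ratio of at least `hi`, `+` at
#' `lo`, `-` below `1/lo`, else `+/-`; speed labels use the inverted
#' sense, `Slow` / `Very slow`).
#'
#' @param results named list of zone time-series data.frames (as in
#'   [run_simulation()]`$series`), one per topography; must include
#'   `"amorphous"` when labels are requested.
#' @param baseline name of the baseline topography (default
#'   `"amorphous"`).
#' @param hi,lo label thresholds on the fold ratio to baseline.
#' @return An object of class `comparison_summary`.
#' @export
compare_topographies <- function(results, baseline = "amorphous",
                                 hi = 1.5, lo = 1.15) {
  if (is.null(names(results)) || any(names(results) == ""))
    stop("compare_topographies: results must be a named list")
  if (!(baseline %in% names(results)))
    stop(sprintf("compare_topographies: missing baseline topography '%s'",
                 baseline))
  per <- lapply(results, function(series) {
    fin <- series_at_end(series)
    rownames(fin) <- fin$zone
    sp <- sqrt(fin$mean_u^2 + fin$mean_v^2)
    data.frame(
      zone = fin$zone, density = fin$liquid_fraction,
      species_mass = fin$species_mass,
      vertical = fin$mean_v, horizontal = -fin$mean_u, speed = sp,
      mean_cell_speed = fin$mean_cell_speed,
      direction = mapply(direction_label, fin$mean_v, -fin$mean_u),
      row.names = fin$zone)
  })
  effs <- lapply(results, recruitment_efficiency)
  tots <- lapply(results, recruitment_totals)
  base <- per[[baseline]]
  topo_rows <- list()
  for (nm in names(results)) {
    d <- per[[nm]]
    for (z in c("interface", "thread")) {
      r_dens <- d[z, "density"] / base[z, "density"]
      r_sp <- d[z, "speed"] / base[z, "speed"]
      r_mass <- if (base[z, "species_mass"] > 0)
        d[z, "species_mass"] / base[z, "species_mass"] else NA_real_
      topo_rows[[paste(nm, z)]] <- data.frame(
        topography = nm, zone = z,
        density = d[z, "density"], density_fold = r_dens,
        density_label = ratio_label(r_dens, hi, lo),
        speed = d[z, "speed"], speed_fold = r_sp,
        speed_label = speed_label(r_sp, hi, lo),
        vector = d[z, "direction"],
        species_mass = d[z, "species_mass"], species_fold = r_mass,
        species_label = ratio_label(r_mass, hi, lo))
    }
  }
  tab <- do.call(rbind, topo_rows)
  rownames(tab) <- NULL
  eff_tab <- do.call(rbind, lapply(names(effs), function(nm) {
    e <- effs[[nm]]; b <- effs[[baseline]]
    data.frame(topography = nm,
               blood_eff_pct = e[["blood"]], species_eff_pct = e[["species"]],
               blood_eff_label = ratio_label(e[["blood"]] / b[["blood"]],
                                             hi, lo),
               species_eff_label = ratio_label(
                 e[["species"]] / b[["species"]], hi, lo))
  }))
  tot_tab <- do.call(rbind, lapply(names(tots), function(nm) {
    data.frame(topography = nm, blood_total = tots[[nm]][["blood"]],
               species_total = tots[[nm]][["species"]])
  }))
  structure(list(zones = tab, efficiency = eff_tab, totals = tot_tab,
                 baseline = baseline, thresholds = c(hi = hi, lo = lo)),
            class = "comparison_summary")
}

#' Render a comparison summary as a text table
#'
#' @param x a [compare_topographies()] result.
#' @param ... unused.
#' @return The lines of the table, invisibly; printed as a side effect.
#' @export
format.comparison_summary <- function(x, ...) {
  z <- x$zones
  topos <- unique(z$topography)
  lines <- c(sprintf(
    "%-14s %-22s %-22s %-24s %-22s %-18s",
    "", "Plasma density", "Velocity", "Vector", "Fibrinogen", "Recruit. eff."),
    sprintf("%-14s %-10s %-11s %-10s %-11s %-11s %-12s %-10s %-11s %-8s %-8s",
            "Topography", "Interface", "Thread", "Interface", "Thread",
            "Interface", "Thread", "Interface", "Thread", "Blood", "Fibr."))
  for (tp in topos) {
    zi <- z[z$topography == tp & z$zone == "interface", ]
    zt <- z[z$topography == tp & z$zone == "thread", ]
    ef <- x$efficiency[x$efficiency$topography == tp, ]
    lines <- c(lines, sprintf(
      "%-14s %-10s %-11s %-10s %-11s %-11s %-12s %-10s %-11s %-8s %-8s",
      tp, zi$density_label, zt$density_label, zi$speed_label, zt$speed_label,
      zi$vector, zt$vector, zi$species_label, zt$species_label,
      ef$blood_eff_label, ef$species_eff_label))
  }
  lines
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(paste(format(x), collapse = "\n"), "\n")
  invisible(x)
}
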