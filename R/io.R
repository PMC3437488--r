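#' Read and write size-binned concentration tables
#'
#' Concentration tables are plain CSV (or TSV) with columns `analyte`,
#' `location`, `state`, `d_lo_um`, `d_hi_um`, `concentration`, `units`; one
#' row per bin, any number of (analyte, location, state) groups per file.
#' Reading validates each group into a [concentration_profile()] (sorted
#' bins, exact non-overlap, non-negative values) and reports offending row
#' numbers; writing is the exact inverse, so write-then-read is lossless.
#'
#' @param path File path.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return `read_concentration_table()`: a named list of
#'   [concentration_profile()]s keyed `analyte.location.state`.
#' @export
read_concentration_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("analyte", "location", "state", "d_lo_um", "d_hi_um",
            "concentration")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$concentration < 0, na.rm = TRUE)) {
    stop("negative concentration at row(s) ",
         paste(which(df$concentration < 0), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  key <- interaction(df$analyte, df$location, df$state, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    o <- order(g$d_lo_um)
    g <- g[o, ]
    bins <- tryCatch(size_bins(g$d_lo_um, g$d_hi_um), error = function(e) {
      stop("invalid bins for group ", g$analyte[1], "/", g$location[1], "/",
           g$state[1], " in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
    concentration_profile(bins, g$concentration, analyte = g$analyte[1],
                          location = g$location[1], state = g$state[1],
                          units = if ("units" %in% names(g)) g$units[1])
  })
  names(out) <- levels(key)
  out
}

#' @rdname read_concentration_table
#' @param profiles A [concentration_profile()] or list of them.
#' @export
write_concentration_table <- function(profiles, path, sep = ",") {
  if (inherits(profiles, "concentration_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    check_profile(p)
    data.frame(analyte = attr(p, "analyte"), location = attr(p, "location"),
               state = attr(p, "state"), d_lo_um = p$d_lo_um,
               d_hi_um = p$d_hi_um, concentration = p$conc,
               units = attr(p, "units"))
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-bin loss-rate tables
#'
#' CSV with columns `d_lo_um`, `d_hi_um`, `k_per_h`.
#'
#' @param path File path.
#' @return `read_loss_rates()`: a [bin_loss_rates()] table.
#' @export
read_loss_rates <- function(path) {
  df <- utils::read.csv(path)
  need <- c("d_lo_um", "d_hi_um", "k_per_h")
  if (!all(need %in% names(df))) {
    stop("loss-rate table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$d_lo_um), ]
  bin_loss_rates(size_bins(df$d_lo_um, df$d_hi_um), df$k_per_h)
}

#' @rdname read_loss_rates
#' @param k A [bin_loss_rates()] table.
#' @export
write_loss_rates <- function(k, path) {
  stopifnot(inherits(k, "bin_loss_rates"))
  utils::write.csv(as.data.frame(k), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an emission profile to CSV
#'
#' Columns `d_lo_um`, `d_hi_um`, `E`, `E_dlogdp`, `flag`.
#'
#' @param E An [emission_profile()].
#' @param path File path.
#' @export
write_emission_profile <- function(E, path) {
  stopifnot(inherits(E, "emission_profile"))
  utils::write.csv(as.data.frame(E), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-bin taxa read counts
#'
#' Long CSV with columns `d_lo_um`, `d_hi_um`, `taxon`, `reads` and optional
#' per-bin `status`, reshaped into an [abundance_table()].
#'
#' @param path File path.
#' @return An [abundance_table()].
#' @export
read_taxa_counts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("d_lo_um", "d_hi_um", "taxon", "reads")
  if (!all(need %in% names(df))) {
    stop("taxa table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  edges <- unique(df[, c("d_lo_um", "d_hi_um")])
  edges <- edges[order(edges$d_lo_um), ]
  bins <- size_bins(edges$d_lo_um, edges$d_hi_um)
  taxa <- sort(unique(df$taxon))
  counts <- matrix(0L, nrow = nrow(bins), ncol = length(taxa),
                   dimnames = list(NULL, taxa))
  ib <- match(df$d_lo_um, bins$d_lo_um)
  counts[cbind(ib, match(df$taxon, taxa))] <- df$reads
  status <- rep("ok", nrow(bins))
  if ("status" %in% names(df)) {
    st <- tapply(df$status, ib, function(s) s[1])
    status[as.integer(names(st))] <- unname(st)
  }
  abundance_table(bins, counts, status)
}

#' Run the full emission-rate pipeline
#'
#' Reproduces the study workflow on any conforming data set: estimate per-bin
#' infiltration factors from the vacant indoor/outdoor pair, invert the
#' well-mixed material balance on the occupied pair for per-person emission
#' rates (per analyte), normalise to `dE/dlog10(dp)`, apportion bacterial
#' emissions to the skin and oral taxa groups when taxa tables are supplied,
#' and estimate bacterial mass fractions when both mass and
#' bacterial-genome profiles are present. Deterministic given its inputs;
#' per-analyte diagnostics record the `f` and `k` used and every per-bin
#' flag.
#'
#' @param concentrations Named list per analyte, each a list with elements
#'   `indoor_occupied`, `outdoor_occupied`, `indoor_vacant`,
#'   `outdoor_vacant` ([concentration_profile()]s) — the structure returned
#'   by [simulate_observations()] — or a path to a concentration CSV
#'   readable by [read_concentration_table()].
#' @param room A [room_params()].
#' @param k A [bin_loss_rates()] table, or `"cubic"` / `"settling"` to derive
#'   one from the corresponding model on the data's bin grid.
#' @param taxa Optional list with `indoor` and `outdoor`
#'   [abundance_table()]s.
#' @param groups Optional list of [taxa_group()]s; defaults to the skin and
#'   oral human-microbiome groups.
#' @param cell_mass_fg Per-bacterium mass for the mass-fraction estimate.
#' @param out_dir Optional directory; when given, emission and group tables
#'   are written there as CSV.
#' @return List with `emissions` (per analyte [emission_profile()]),
#'   `infiltration` (per analyte), `group_emissions`, `enrichment`,
#'   `mass_fraction`, `diagnostics`.
#' @export
run_pipeline <- function(concentrations, room, k = "cubic", taxa = NULL,
                         groups = NULL, cell_mass_fg = 655, out_dir = NULL) {
  if (is.character(concentrations) && length(concentrations) == 1L) {
    concentrations <- regroup_profiles(read_concentration_table(concentrations))
  }
  if (!length(concentrations)) stop("no concentration data", call. = FALSE)
  first <- concentrations[[1]]$indoor_occupied
  if (is.null(first)) {
    stop("each analyte needs indoor_occupied/outdoor_occupied/",
         "indoor_vacant/outdoor_vacant profiles", call. = FALSE)
  }
  bins <- as_size_bins(first)
  if (is.character(k)) {
    k <- switch(match.arg(k, c("cubic", "settling")),
                cubic = suppressMessages(deposition_loss_rates(bins)),
                settling = bin_loss_rates(
                  bins, settling_bin_average(bins)$k_per_h))
  }
  stop_if_bins_differ(bins, k, "concentrations and k")

  emissions <- list(); infiltration <- list(); diagnostics <- list()
  for (an in names(concentrations)) {
    set <- concentrations[[an]]
    need <- c("indoor_occupied", "outdoor_occupied", "indoor_vacant",
              "outdoor_vacant")
    have <- need %in% names(set)
    if (!all(have)) {
      stop("analyte ", an, ": missing ", paste(need[!have], collapse = ", "),
           "; infiltration factors require the vacant indoor/outdoor pair",
           call. = FALSE)
    }
    f <- infiltration_factors(set$indoor_vacant, set$outdoor_vacant)
    E <- invert_emission(set$indoor_occupied, set$outdoor_occupied, f,
                         room, k)
    emissions[[an]] <- E
    infiltration[[an]] <- f
    diagnostics[[an]] <- list(f = f, k = k, flags = E$flag,
                              raw_E = attr(E, "raw"))
  }

  group_emissions <- NULL; enrichment <- NULL
  if (!is.null(taxa) && "bacterial_genomes" %in% names(emissions)) {
    groups <- groups %||% list(skin = skin_taxa_group(),
                               oral = oral_taxa_group())
    E_bact <- emissions$bacterial_genomes
    group_emissions <- lapply(groups, function(g) {
      ga <- group_abundance(taxa$indoor, g)
      apportion_emissions(E_bact, ga$per_bin, g)
    })
    enrichment <- lapply(groups, function(g) {
      enrichment_factor(group_abundance(taxa$indoor, g)$overall,
                        group_abundance(taxa$outdoor, g)$overall)
    })
  }

  mass_fraction <- NULL
  if (all(c("mass", "bacterial_genomes") %in% names(concentrations))) {
    bact <- concentrations$bacterial_genomes$indoor_occupied$conc
    pm <- concentrations$mass$indoor_occupied$conc
    mass_fraction <- ppm_fraction(
      bacterial_mass_concentration(bact, cell_mass_fg), pm)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (an in names(emissions)) {
      write_emission_profile(emissions[[an]],
                             file.path(out_dir, paste0("emissions_", an,
                                                       ".csv")))
    }
    for (gn in names(group_emissions %||% list())) {
      utils::write.csv(as.data.frame(group_emissions[[gn]]),
                       file.path(out_dir, paste0("group_emissions_", gn,
                                                 ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }

  list(emissions = emissions, infiltration = infiltration,
       group_emissions = group_emissions, enrichment = enrichment,
       mass_fraction = mass_fraction, diagnostics = diagnostics)
}

# read_concentration_table() returns a flat analyte.location.state list;
# regroup into the per-analyte nested structure run_pipeline() consumes.
regroup_profiles <- function(flat) {
  out <- list()
  for (p in flat) {
    an <- attr(p, "analyte")
    slot <- paste(attr(p, "location"), attr(p, "state"), sep = "_")
    out[[an]][[slot]] <- p
  }
  out
}

#' Read room and pipeline options from a YAML config
#'
#' Minimal YAML schema: required keys `volume_m3`, `aer_per_h`, `occupancy`
#' (the [room_params()] fields); optional `k_source` (`"cubic"` or
#' `"settling"`), `cell_mass_fg`, and `staph_in_oral` (logical, move
#' Staphylococcus to the oral group). Unknown keys are preserved under
#' `$extra` so callers can layer their own options.
#'
#' @param path Path to a YAML file.
#' @return List with `room` ([room_params()]), `k_source`, `cell_mass_fg`,
#'   `groups` (list of [taxa_group()]s), `extra`.
#' @export
read_room_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("volume_m3", "aer_per_h", "occupancy")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys)) {
    stop("config ", path, " is missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  staph_oral <- isTRUE(cfg$staph_in_oral)
  known <- c(need, "k_source", "cell_mass_fg", "staph_in_oral")
  list(room = room_params(cfg$volume_m3, cfg$aer_per_h, cfg$occupancy),
       k_source = cfg$k_source %||% "cubic",
       cell_mass_fg = cfg$cell_mass_fg %||% 655,
       groups = list(skin = skin_taxa_group(staph = !staph_oral),
                     oral = oral_taxa_group(staph = staph_oral)),
       extra = cfg[setdiff(names(cfg), known)])
}

#' Published classroom microflora emission rates (example data)
#'
#' Per-person, per-bin emission rates of skin/hair/nostril and oral-cavity
#' bacteria measured in an occupied university classroom field study,
#' shipped as a plain-text example table. Columns: `d_lo_um`, `d_hi_um`,
#' `group`, `E_million_per_h_person` (NA where the group was not detected or
#' the stage failed PCR), `pct_of_total` (percent of total bacterial
#' emissions in that bin). Used by the worked examples to demonstrate
#' group-total reconstruction.
#'
#' @return Data frame with one row per (bin, group).
#' @export
classroom_microflora_emissions <- function() {
  path <- system.file("extdata", "classroom_microflora_emissions.csv",
                      package = "bioaer", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
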