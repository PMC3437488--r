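#' Per-bin taxa read-count table
#'
#' Read counts per (size bin, taxon) from amplicon sequencing of the
#' impactor stages, with a per-bin status: `"ok"`, `"failed_pcr"` (the stage
#' did not amplify before sequencing) or `"not_detected"`. Counts in non-ok
#' bins are ignored; proportions are never computed for them and they carry
#' their status through every downstream summary.
#'
#' @param bins A [size_bins()] grid.
#' @param counts Integer matrix, one row per bin, one named column per taxon.
#' @param status Per-bin character vector; default all `"ok"`.
#' @return Object of class `abundance_table`: list with `bins`, `counts`,
#'   `status`.
#' @export
abundance_table <- function(bins, counts, status = NULL) {
  bins <- as_size_bins(bins)
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(bins)) {
    stop("counts must have one row per bin", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    stop("counts columns must be named by taxon", call. = FALSE)
  }
  if (any(counts < 0, na.rm = TRUE) ||
      any(counts != round(counts), na.rm = TRUE)) {
    stop("read counts must be non-negative integers", call. = FALSE)
  }
  status <- status %||% rep("ok", nrow(bins))
  if (!all(status %in% c("ok", "failed_pcr", "not_detected"))) {
    stop("bin status must be ok, failed_pcr or not_detected", call. = FALSE)
  }
  if (any(status == "ok" & rowSums(counts, na.rm = TRUE) == 0)) {
    stop("an ok bin has zero total reads; mark it failed_pcr or not_detected",
         call. = FALSE)
  }
  structure(list(bins = bins, counts = counts, status = status),
            class = "abundance_table")
}

#' Per-bin relative abundances
#'
#' Proportions `counts / bin total` for each ok bin; rows for failed or
#' not-detected bins are all-NA and keep their status.
#'
#' @param table An [abundance_table()].
#' @return Matrix of proportions (rows sum to 1 for ok bins) with a `status`
#'   attribute.
#' @export
relative_abundances <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  props <- table$counts / rowSums(table$counts)
  props[table$status != "ok", ] <- NA_real_
  attr(props, "status") <- table$status
  props
}

#' Taxa group definition
#'
#' A named set of taxon labels summarised together, e.g. the
#' human-microbiome source groups below. Members absent from a table's taxon
#' namespace are warned about and contribute zero.
#'
#' @param name Group name.
#' @param members Character vector of taxon labels.
#' @return Object of class `taxa_group`.
#' @export
taxa_group <- function(name, members) {
  if (length(members) == 0) stop("a taxa group needs members", call. = FALSE)
  structure(list(name = name, members = unique(members)),
            class = "taxa_group")
}

#' Human-microbiome source groups
#'
#' Default groupings of airborne bacterial taxa by human body-site origin:
#'
#' * skin/hair/nostrils — Propionibacterineae, Staphylococcus,
#'   Enterobacteriaceae, Corynebacterineae;
#' * oral cavity — Pasteurellaceae, Fusobacterium, Veillonella.
#'
#' *Staphylococcus* has both skin and oral-cavity sources; by default it is
#' assigned to the skin group, and `staph` lets the caller move or duplicate
#' it into the oral group so both conventions can be compared.
#'
#' @param staph For `skin_taxa_group()`: include Staphylococcus (default
#'   TRUE). For `oral_taxa_group()`: include it (default FALSE).
#' @return A [taxa_group()].
#' @export
skin_taxa_group <- function(staph = TRUE) {
  members <- c("Propionibacterineae", "Enterobacteriaceae",
               "Corynebacterineae")
  if (staph) members <- c(members, "Staphylococcus")
  taxa_group("skin_hair_nostrils", members)
}

#' @rdname skin_taxa_group
#' @export
oral_taxa_group <- function(staph = FALSE) {
  members <- c("Pasteurellaceae", "Fusobacterium", "Veillonella")
  if (staph) members <- c(members, "Staphylococcus")
  taxa_group("oral_cavity", members)
}

#' Group relative abundance per bin and overall
#'
#' Per bin, the summed relative abundance of the group's member taxa. The
#' overall (across-bin) fraction is computed two ways: pooling member reads
#' over all ok bins and dividing by pooled total reads (the default summary —
#' with shallow, uneven per-bin depth pooling weights every read equally),
#' and the unweighted mean of per-bin fractions. Both are returned; `pooled`
#' selects which one `overall` aliases.
#'
#' @param table An [abundance_table()].
#' @param group A [taxa_group()].
#' @param pooled Use read pooling for the `overall` summary (default TRUE).
#' @return List with `per_bin` (NA for non-ok bins), `overall`,
#'   `overall_pooled`, `overall_mean`, `group`.
#' @export
group_abundance <- function(table, group, pooled = TRUE) {
  stopifnot(inherits(table, "abundance_table"), inherits(group, "taxa_group"))
  hit <- group$members %in% colnames(table$counts)
  if (!all(hit)) {
    warning("taxa group '", group$name, "' members not in table: ",
            paste(group$members[!hit], collapse = ", "), call. = FALSE)
  }
  members <- group$members[hit]
  ok <- table$status == "ok"
  member_reads <- if (length(members)) {
    rowSums(table$counts[, members, drop = FALSE])
  } else rep(0, nrow(table$counts))
  total_reads <- rowSums(table$counts)
  per_bin <- ifelse(ok, member_reads / total_reads, NA_real_)
  overall_pooled <- if (any(ok)) sum(member_reads[ok]) / sum(total_reads[ok])
    else NA_real_
  overall_mean <- mean(per_bin, na.rm = TRUE)
  list(per_bin = per_bin,
       overall = if (pooled) overall_pooled else overall_mean,
       overall_pooled = overall_pooled,
       overall_mean = overall_mean,
       group = group)
}

#' Apportion total emissions to a taxa group
#'
#' Multiplies the per-bin total bacterial-genome emission rate by the group's
#' per-bin relative abundance, giving a per-bin, per-person emission rate for
#' that source group. Bins with missing fractions (failed PCR, not detected)
#' or missing totals carry NA and are excluded from the group total, which is
#' the sum over bins with data.
#'
#' @param E_total An [emission_profile()] of total emissions.
#' @param group_fraction Per-bin fractions in `[0, 1]` (NA allowed), e.g.
#'   `group_abundance(...)$per_bin`.
#' @param group Optional [taxa_group()] for labelling.
#' @return Data frame of class `group_emission_profile` with columns
#'   `d_lo_um`, `d_hi_um`, `E_group`, `pct_of_total`, plus attributes
#'   `total_E` (sum over non-missing bins) and `group`.
#' @export
apportion_emissions <- function(E_total, group_fraction, group = NULL) {
  stopifnot(inherits(E_total, "emission_profile"))
  if (length(group_fraction) != nrow(E_total)) {
    stop("one fraction per bin required", call. = FALSE)
  }
  if (any(group_fraction < 0 | group_fraction > 1, na.rm = TRUE)) {
    stop("group fractions must lie in [0, 1]", call. = FALSE)
  }
  E_group <- E_total$E * group_fraction
  out <- data.frame(d_lo_um = E_total$d_lo_um, d_hi_um = E_total$d_hi_um,
                    E_group = E_group,
                    pct_of_total = 100 * group_fraction)
  structure(out,
            total_E = sum(E_group, na.rm = TRUE),
            group = group,
            units = attr(E_total, "units"),
            class = c("group_emission_profile", "size_bins", "data.frame"))
}

#' Total emission rate of a group profile
#'
#' Sum of per-bin group emission rates over bins with data (NA bins — failed
#' PCR or not detected — contribute nothing, by convention).
#'
#' @param x A `group_emission_profile` (or any data frame with `E_group`).
#' @return Scalar total emission rate.
#' @export
total_emission <- function(x) {
  sum(x$E_group, na.rm = TRUE)
}

#' Indoor/outdoor enrichment factor
#'
#' Ratio of a group's indoor relative abundance to its outdoor relative
#' abundance; values above 1 mean the group is enriched in indoor air. A zero
#' outdoor fraction leaves the factor undefined (NA, with the indoor value
#' attached for reporting).
#'
#' @param indoor_fraction,outdoor_fraction Group fractions (same scale, e.g.
#'   both proportions or both percent).
#' @return Dimensionless ratio, or NA with attribute `indoor_fraction` when
#'   the outdoor fraction is zero.
#' @examples
#' enrichment_factor(0.17, 0.049)  # 3.5
#' @export
enrichment_factor <- function(indoor_fraction, outdoor_fraction) {
  if (indoor_fraction < 0 || outdoor_fraction < 0) {
    stop("fractions must be non-negative", call. = FALSE)
  }
  if (outdoor_fraction == 0) {
    return(structure(NA_real_, indoor_fraction = indoor_fraction))
  }
  indoor_fraction / outdoor_fraction
}
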