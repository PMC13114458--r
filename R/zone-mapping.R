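# Anatomic-zone to MRI-subcompartment mapping, aggregation of zone-level
# pathway scores to patient x subcompartment observations, and the
# composition-baseline diagnostic.

#' Zone-to-subcompartment map
#'
#' The primary map follows the biological rationale of the design: the
#' enhancing tumor (ET) receives the cellular tumor and microvascular
#' proliferation zones (CT, CTmvp), the non-enhancing tumor (NET) receives
#' pseudopalisading necrosis (CTpan), and peritumoral edema (ED) receives
#' infiltrating tumor and leading edge (IT, LE).
#'
#' @param mapping Named character vector `zone -> subcompartment`.
#' @param aggregation `"mean"` or `"median"` across zones within a
#'   subcompartment.
#' @param variant Label (`"primary"`, `"S1a"`, `"S1b"`, ...).
#' @return An `rg_zone_map` object.
#' @export
zone_map <- function(mapping = c(CT = "ET", CTmvp = "ET", CTpan = "NET",
                                 IT = "ED", LE = "ED"),
                     aggregation = c("mean", "median"),
                     variant = "primary") {
  aggregation <- match.arg(aggregation)
  if (!all(mapping %in% c("ET", "NET", "ED"))) {
    abort("Subcompartments must be ET, NET or ED.")
  }
  if (!"ET" %in% mapping) abort("ET must receive at least one zone.")
  structure(list(mapping = mapping, aggregation = aggregation,
                 variant = variant),
            class = "rg_zone_map")
}

primary_zone_map <- function(aggregation = "mean") zone_map(aggregation = aggregation)

#' @export
print.rg_zone_map <- function(x, ...) {
  cat(sprintf("<rg_zone_map> variant=%s aggregation=%s\n", x$variant,
              x$aggregation))
  for (z in names(x$mapping)) cat(sprintf("  %-6s -> %s\n", z, x$mapping[z]))
  invisible(x)
}

#' Aggregate zone-level pathway scores to patient x subcompartment
#'
#' Replicate samples within one patient-zone are averaged first (so
#' patients with more replicates do not dominate), then the available
#' mapped zones are combined by the map's aggregation function. A row is
#' emitted only for subcompartments with at least one contributing zone;
#' the contributing zones are recorded in `zones` (joined with `+`) and
#' counted in `n_zones`.
#'
#' @param scores Long score tibble from [ssgsea_scores()] including
#'   `patient_id` and `zone`.
#' @param map An [zone_map()]; samples from unmapped zones are dropped
#'   with a warning.
#' @return The observation table: one row per patient x subcompartment x
#'   gene set with columns `patient_id`, `subcompartment`, `set_name`,
#'   `score`, `n_zones`, `zones`.
#' @export
aggregate_to_subcompartments <- function(scores, map = zone_map()) {
  stopifnot(all(c("patient_id", "zone", "set_name", "score") %in%
                  names(scores)))
  unmapped <- setdiff(unique(scores$zone), names(map$mapping))
  if (length(unmapped)) {
    warn(sprintf("Dropping samples from unmapped zone(s): %s",
                 paste(unmapped, collapse = ", ")))
  }
  agg_fun <- if (map$aggregation == "mean") mean else median
  obs <- scores |>
    filter(.data$zone %in% names(map$mapping)) |>
    # replicate LMD samples within a zone are averaged first
    summarise(score = mean(.data$score),
              .by = c("patient_id", "zone", "set_name")) |>
    mutate(subcompartment = unname(map$mapping[.data$zone])) |>
    arrange(factor(.data$zone, levels = names(map$mapping))) |>
    summarise(score = agg_fun(.data$score),
              n_zones = dplyr::n_distinct(.data$zone),
              zones = paste(unique(.data$zone), collapse = "+"),
              .by = c("patient_id", "subcompartment", "set_name")) |>
    arrange(.data$set_name, .data$patient_id,
            factor(.data$subcompartment, levels = c("ET", "NET", "ED")))
  if (!nrow(obs)) abort("No mappable samples; observation table is empty.")
  obs
}

#' Composition baseline test
#'
#' Spearman correlation between each patient's pathway score and a numeric
#' indicator of the composition of its aggregated score, diagnosing whether
#' an apparent pathway signal merely tracks which zones happened to be
#' available for a patient. The default indicator is the number of distinct
#' zones contributing to the patient's score (restricted to one
#' subcompartment via `subcompartment`); `indicator = "has_ctmvp"` uses a
#' binary CTmvp-availability indicator instead.
#'
#' @param obs Observation table from [aggregate_to_subcompartments()].
#' @param set_name Gene set to test.
#' @param indicator `"n_zones"` (default) or `"has_ctmvp"`.
#' @param subcompartment Optional subcompartment to restrict to (e.g.
#'   `"ET"`); by default the patient-level mean score and total zone count
#'   across subcompartments are used.
#' @return A one-row tibble (`set_name`, `indicator`, `rho`, `p`, `n`,
#'   `applicable`); a constant indicator yields `applicable = FALSE` with
#'   `rho`/`p` equal to `NA`.
#' @export
composition_baseline_test <- function(obs, set_name,
                                      indicator = c("n_zones", "has_ctmvp"),
                                      subcompartment = NULL) {
  indicator <- match.arg(indicator)
  d <- obs |> filter(.data$set_name == !!set_name)
  if (!is.null(subcompartment)) {
    d <- d |> filter(.data$subcompartment == !!subcompartment)
  }
  if (!nrow(d)) abort(sprintf("No observations for set %s.", set_name))
  pat <- d |>
    summarise(score = mean(.data$score),
              n_zones = sum(.data$n_zones),
              has_ctmvp = as.numeric(any(grepl("CTmvp", .data$zones))),
              .by = "patient_id")
  if (nrow(pat) < 4) abort("Composition test needs >= 4 patients.")
  ind <- pat[[indicator]]
  if (sd(ind) == 0) {
    return(tibble(set_name = set_name, indicator = indicator,
                  rho = NA_real_, p = NA_real_, n = nrow(pat),
                  applicable = FALSE))
  }
  st <- spearman_test(pat$score, ind)
  tibble(set_name = set_name, indicator = indicator, rho = st$rho,
         p = st$p, n = st$n, applicable = TRUE)
}
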