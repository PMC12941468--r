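# Carbon accounting: per-individual carbonate carbon and panel aggregation.

#' Carbonate carbon of one individual
#'
#' `C = W * carbon_fraction` grams.
#'
#' @param dry_weight_g shell dry weight(s), grams.
#' @param params one-row registry tibble, or a bare carbon fraction.
#' @return carbonate carbon in grams.
#' @export
individual_carbon <- function(dry_weight_g, params) {
  if (any(dry_weight_g < 0)) {
    abort("dry weight must be non-negative", class = "shellcarbon_data_error")
  }
  frac <- if (is.numeric(params)) params else params$carbon_fraction
  dry_weight_g * frac
}

#' Carbon report from measured dimensions
#'
#' Builds the per-individual carbon table directly from a dimension table
#' (species, `L_mm`, `B_mm`), chaining attachment area -> allometric dry
#' weight -> carbonate carbon with the registry parameters.
#'
#' @param dims data frame with columns `class` (or `species`), `L_mm`,
#'   `B_mm`; an `area_cm2` column is recomputed if absent.
#' @param registry species parameter registry (default [builtin_params()]).
#' @param meta panel metadata list carried into the report.
#' @return a `panel_carbon_report`.
#' @export
carbon_from_dimensions <- function(dims, registry = builtin_params(),
                                   meta = list()) {
  dims <- tibble::as_tibble(dims)
  if (!"class" %in% names(dims) && "species" %in% names(dims)) {
    dims <- rename(dims, class = "species")
  }
  missing <- setdiff(unique(dims$class), registry$species)
  if (length(missing)) {
    abort(sprintf("species missing from the registry: %s",
                  paste(missing, collapse = ", ")),
          class = "shellcarbon_config_error")
  }
  records <- dims |>
    mutate(area_cm2 = attachment_area_cm2(.data$L_mm, .data$B_mm)) |>
    left_join(registry, by = c(class = "species")) |>
    mutate(
      dry_weight_g = .data$valve_factor * .data$alpha *
        .data$area_cm2^.data$beta,
      carbon_g = .data$dry_weight_g * .data$carbon_fraction
    ) |>
    rename(species = "class") |>
    select(dplyr::any_of("instance_id"), "species", "L_mm", "B_mm",
           "area_cm2", "dry_weight_g", "carbon_g")
  new_panel_report(records, meta)
}

#' Full panel carbon report from segmented instances
#'
#' Chains [dimension_table()] (mask -> projected L, B), the allometric
#' dry-weight model and the carbon fraction, then aggregates per species
#' and over the panel.
#'
#' @param instances instance table (segmented and classified).
#' @param scale_px_per_cm pixel scale of the panel.
#' @param registry species parameter registry.
#' @param meta panel metadata list (e.g. `group`, `date`).
#' @return a `panel_carbon_report`.
#' @export
panel_report <- function(instances, scale_px_per_cm,
                         registry = builtin_params(), meta = list()) {
  missing <- setdiff(unique(instances$class), registry$species)
  if (length(missing)) {
    abort(sprintf("species missing from the registry: %s",
                  paste(missing, collapse = ", ")),
          class = "shellcarbon_config_error")
  }
  dims <- dimension_table(instances, scale_px_per_cm)
  carbon_from_dimensions(dims, registry, meta)
}

new_panel_report <- function(records, meta) {
  summary <- records |>
    group_by(.data$species) |>
    summarise(n = dplyr::n(),
              dry_weight_g = sum(.data$dry_weight_g),
              carbon_g = sum(.data$carbon_g), .groups = "drop")
  structure(
    list(meta = meta, records = records, summary = summary,
         totals = tibble::tibble(
           n = nrow(records),
           dry_weight_g = sum(records$dry_weight_g),
           carbon_g = sum(records$carbon_g))),
    class = "panel_carbon_report"
  )
}

#' @export
print.panel_carbon_report <- function(x, ...) {
  cat(sprintf("<panel_carbon_report> %d individual(s), %.4f g dry weight, %.4f g carbonate carbon\n",
              x$totals$n, x$totals$dry_weight_g, x$totals$carbon_g))
  print(x$summary)
  invisible(x)
}

#' @method tidy panel_carbon_report
#' @export
tidy.panel_carbon_report <- function(x, ...) x$records

#' @method glance panel_carbon_report
#' @export
glance.panel_carbon_report <- function(x, ...) {
  out <- x$totals
  for (nm in names(x$meta)) out[[nm]] <- x$meta[[nm]]
  out
}

#' Relative error of an estimate against a reference measurement
#'
#' @param estimated_g,measured_g masses in grams; `measured_g` must be
#'   positive.
#' @return percent relative error `|estimated - measured| / measured * 100`.
#' @export
relative_error <- function(estimated_g, measured_g) {
  if (any(measured_g <= 0)) {
    abort("reference measurement must be positive",
          class = "shellcarbon_data_error")
  }
  abs(estimated_g - measured_g) / measured_g * 100
}

#' Compare panels across months or materials
#'
#' Summarises a collection of panel reports by a metadata key: mean
#' abundance (individuals per panel) and mean carbonate carbon (g per
#' panel), unweighted over the panels present in each group.
#'
#' @param reports list of `panel_carbon_report` objects.
#' @param by metadata field to group on (e.g. `"month"`, `"group"`).
#' @param expected_groups optional vector of groups that must appear;
#'   missing ones are reported with zero means and `missing = TRUE`.
#' @return tibble with `n_panels`, `mean_abundance`, `mean_carbon_g`,
#'   `mean_dry_weight_g` per group, sorted by the key.
#' @export
comparison_table <- function(reports, by = "group", expected_groups = NULL) {
  if (length(reports) == 0L) {
    return(tibble::tibble(!!by := character(), n_panels = integer(),
                          mean_abundance = double(), mean_carbon_g = double(),
                          mean_dry_weight_g = double(), missing = logical()))
  }
  rows <- purrr::map(reports, function(r) {
    key <- r$meta[[by]]
    if (is.null(key)) {
      abort(sprintf("a report lacks metadata field '%s'", by),
            class = "shellcarbon_config_error")
    }
    tibble::tibble(!!by := as.character(key), n = r$totals$n,
                   carbon_g = r$totals$carbon_g,
                   dry_weight_g = r$totals$dry_weight_g)
  }) |> dplyr::bind_rows()
  out <- rows |>
    group_by(across(all_of(by))) |>
    summarise(n_panels = dplyr::n(),
              mean_abundance = mean(.data$n),
              mean_carbon_g = mean(.data$carbon_g),
              mean_dry_weight_g = mean(.data$dry_weight_g),
              .groups = "drop") |>
    mutate(missing = FALSE)
  absent <- setdiff(as.character(expected_groups), out[[by]])
  if (length(absent)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      !!by := absent, n_panels = 0L, mean_abundance = 0,
      mean_carbon_g = 0, mean_dry_weight_g = 0, missing = TRUE))
  }
  arrange(out, across(all_of(by)))
}
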