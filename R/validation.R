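#' Random leaf-level train/validation split
#'
#' Simple random sample of the leaves eligible for a trait (those with a
#' non-missing trait value and a spectrum): `frac` of them train, the rest
#' validate — the conventional split design for spectra-trait models.
#'
#' @param dataset A data frame with one row per leaf including `leaf_id`
#'   and the trait column.
#' @param trait Trait column name; rows with `NA` are ineligible.
#' @param frac Training fraction (default 0.8).
#' @param seed Integer seed; membership is reproducible given it.
#' @return A list of class `split_spec`: `kind`, `train` and `validation`
#'   character vectors of `leaf_id`, `trait`, `seed`.
#' @export
make_random_split <- function(dataset, trait, frac = 0.8, seed = 1) {
  ids <- eligible_ids(dataset, trait)
  if (length(ids) < 5) stop("too few eligible leaves to split", call. = FALSE)
  set.seed(seed)
  n_train <- floor(frac * length(ids))
  train <- sort(sample(ids, n_train))
  new_split("random", train, setdiff(ids, train), trait, seed)
}

#' Species-holdout train/validation split
#'
#' Tests model transfer to unseen species: the "new" species are those
#' whose leaves were all measured in the most recent campaign (none in any
#' earlier campaign); a fraction of them (rounded half away from zero) is
#' drawn at random and *all* leaves of the drawn species form the
#' validation set, every other leaf trains. Species measured in both an
#' earlier campaign and the recent one are never held out.
#'
#' @param dataset Per-leaf data frame with `leaf_id`, `species`,
#'   `campaign` and the trait column.
#' @param trait Trait column name.
#' @param new_species_frac Fraction of new species held out (default 0.3).
#' @param seed Integer seed.
#' @param new_campaign Campaign label defining "new" species (default the
#'   lexicographically last campaign present).
#' @return A `split_spec`; also carries `holdout_species`.
#' @export
make_species_split <- function(dataset, trait, new_species_frac = 0.3,
                               seed = 1, new_campaign = NULL) {
  stopifnot(all(c("species", "campaign") %in% names(dataset)))
  if (is.null(new_campaign)) {
    new_campaign <- max(as.character(dataset$campaign))
  }
  by_species <- dplyr::summarise(
    dplyr::group_by(dataset, .data$species),
    only_new = all(.data$campaign == new_campaign),
    .groups = "drop"
  )
  new_species <- by_species$species[by_species$only_new]
  if (length(new_species) == 0) stop("no new species to hold out",
                                     call. = FALSE)
  n_hold <- round_half_up(new_species_frac * length(new_species))
  set.seed(seed)
  holdout <- sort(sample(new_species, n_hold))

  ids <- eligible_ids(dataset, trait)
  sp <- dataset$species[match(ids, dataset$leaf_id)]
  val <- ids[sp %in% holdout]
  sp <- new_split("species", setdiff(ids, val), val, trait, seed)
  sp$holdout_species <- holdout
  sp$n_new_species <- length(new_species)
  sp
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Site-holdout train/validation split
#'
#' The hardest transfer test: all Panama leaves train, all Brazil leaves
#' validate — different spectrometer, species and site. Deterministic
#' (no randomness). The split refuses traits with no validation-site data
#' (dark respiration was never measured in Brazil) and warns when the
#' validation site is sparse for a trait.
#'
#' @param dataset Per-leaf data frame with `leaf_id`, `site` and the trait
#'   column. Sites starting with `"Brazil"` validate; all others train.
#' @param trait Trait column name.
#' @param min_validation Warn below this many validation leaves.
#' @return A `split_spec`.
#' @export
make_site_split <- function(dataset, trait, min_validation = 10) {
  stopifnot("site" %in% names(dataset))
  ids <- eligible_ids(dataset, trait)
  is_val <- grepl("^Brazil", dataset$site[match(ids, dataset$leaf_id)])
  if (!any(is_val)) {
    stop("site split unavailable for '", trait,
         "': no validation-site observations", call. = FALSE)
  }
  if (sum(is_val) < min_validation) {
    warning("only ", sum(is_val), " validation-site leaves for '", trait,
            "'; site-split metrics will be fragile")
  }
  new_split("site", ids[!is_val], ids[is_val], trait, seed = NA_integer_)
}

eligible_ids <- function(dataset, trait) {
  if (!trait %in% names(dataset)) {
    stop("dataset has no trait column '", trait, "'", call. = FALSE)
  }
  as.character(dataset$leaf_id[!is.na(dataset[[trait]])])
}

new_split <- function(kind, train, validation, trait, seed) {
  stopifnot(length(intersect(train, validation)) == 0L)
  structure(
    list(kind = kind, train = as.character(train),
         validation = as.character(validation), trait = trait, seed = seed),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat("Split (", x$kind, ") for ", x$trait, ": ", length(x$train),
      " train / ", length(x$validation), " validation leaves\n", sep = "")
  invisible(x)
}

#' Validation metrics: R-squared, RMSE and range-normalized RMSE
#'
#' RMSE is the root mean squared prediction error on the validation set;
#' %RMSE standardizes it by the trait range (max - min) over the *whole*
#' dataset, all splits pooled, so the three split designs are comparable;
#' R-squared is 1 - SSres/SStot on the validation observations (not a
#' squared correlation — it penalizes bias and can be negative; it is
#' never clipped).
#'
#' @param observed,predicted Paired finite numeric vectors (n >= 2).
#' @param whole_range Trait range (max - min) across the whole dataset,
#'   used for %RMSE; must be > 0.
#' @param trait,split Optional labels carried into the report.
#' @param n_obs,n_comp Optional bookkeeping columns (total observations,
#'   component count).
#' @return A one-row tibble: `trait`, `split`, `n_obs`, `n_val`, `n_comp`,
#'   `rmse`, `range`, `pct_rmse`, `r2`.
#' @export
compute_metrics <- function(observed, predicted, whole_range,
                            trait = NA_character_, split = NA_character_,
                            n_obs = NA_integer_, n_comp = NA_integer_) {
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 2) stop("need at least 2 paired values",
                                 call. = FALSE)
  if (!is.finite(whole_range) || whole_range <= 0) {
    stop("whole_range must be a positive number", call. = FALSE)
  }
  rmse <- sqrt(mean((observed - predicted)^2))
  sstot <- sum((observed - mean(observed))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum((observed - predicted)^2) / sstot
  if (sstot == 0) warning("zero-variance observed vector; R2 undefined")
  tibble::tibble(
    trait = trait, split = split,
    n_obs = n_obs, n_val = length(observed), n_comp = n_comp,
    rmse = rmse, range = whole_range,
    pct_rmse = 100 * rmse / whole_range, r2 = r2
  )
}

#' Species-by-campaign composition summary
#'
#' Bookkeeping used throughout the validation designs: counts leaves per
#' species and campaign (long input, one row per leaf) or reads an
#' already-tabulated wide composition table, and reports total species,
#' per-campaign species counts, and the "new species" of the most recent
#' campaign (present there and in no earlier campaign).
#'
#' @param composition Either a per-leaf data frame with `species` and
#'   `campaign`, or a wide count table whose first column is `species` and
#'   remaining columns are campaign leaf counts (`NA` or 0 = not sampled).
#' @return A list: `n_species`, `by_campaign` (named integer vector of
#'   species counts), `new_species` (character vector for the last
#'   campaign column/label), `leaf_counts` (long tibble `species`,
#'   `campaign`, `n_leaves`).
#' @export
species_composition <- function(composition) {
  if (all(c("species", "campaign") %in% names(composition))) {
    counts <- dplyr::count(composition, .data$species, .data$campaign,
                           name = "n_leaves")
  } else {
    stopifnot(names(composition)[1] == "species")
    counts <- tidyr::pivot_longer(composition, cols = -1,
                                  names_to = "campaign",
                                  values_to = "n_leaves")
    counts <- counts[!is.na(counts$n_leaves) & counts$n_leaves > 0, ]
  }
  campaigns <- sort(unique(as.character(counts$campaign)))
  by_campaign <- vapply(campaigns, function(cc) {
    length(unique(counts$species[counts$campaign == cc]))
  }, integer(1))
  last <- campaigns[length(campaigns)]
  in_last <- unique(counts$species[counts$campaign == last])
  in_earlier <- unique(counts$species[counts$campaign != last])
  list(
    n_species = length(unique(counts$species)),
    by_campaign = by_campaign,
    new_species = sort(setdiff(in_last, in_earlier)),
    leaf_counts = tibble::as_tibble(counts)
  )
}

#' Split membership as a tidy table
#'
#' @param split A `split_spec`.
#' @return A tibble `leaf_id`, `role` (`"train"` / `"validation"`).
#' @export
split_membership <- function(split) {
  stopifnot(inherits(split, "split_spec"))
  tibble::tibble(
    leaf_id = c(split$train, split$validation),
    role = rep(c("train", "validation"),
               c(length(split$train), length(split$validation)))
  )
}
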