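# Specimen-level measurements -> species-level trait tables, and literature
# behaviour records -> binary social characters.
#
# The measurement scheme mirrors standard museum-skin morphometrics: bilateral
# traits (outer tail, tarsus) measured on both sides and averaged per
# specimen; tail-fork depth derived per specimen as mean outer tail length
# minus middle tail length (its sign is meaningful: <= 0 for square or rounded
# tails); sexes pooled with equal weight per specimen when averaging up to
# species.

.SPECIMEN_COLS <- c("species", "sex", "wing", "outer_tail_L", "outer_tail_R",
                    "middle_tail", "tarsus_L", "tarsus_R", "bill_length",
                    "bill_width")
.BEHAVIOR_COLS <- c("species", "max_breeding_pairs", "cavity_override",
                    "foraging_category")

#' Trait names produced by the specimen pipeline
#' @export
trait_names <- function() {
  c("wing", "outer_tail", "tail_fork", "tarsus", "bill_length", "bill_width")
}

#' Read a specimen measurement CSV
#'
#' Expected columns: `species, sex, wing, outer_tail_L, outer_tail_R,
#' middle_tail, tarsus_L, tarsus_R, bill_length, bill_width` (measurements in
#' mm; any measurement may be missing). Non-numeric measurement cells become
#' missing values. Multiple rows per species are expected (one per specimen).
#'
#' @param path CSV file path.
#' @return data.frame of specimen records.
#' @export
read_specimen_csv <- function(path) {
  if (!file.exists(path)) stop("specimen file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty specimen file: ", path)
  missing_cols <- setdiff(.SPECIMEN_COLS, names(df))
  if (length(missing_cols)) {
    stop("specimen CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$species <- trimws(as.character(df$species))
  if (any(!nzchar(df$species))) stop("empty species label in specimen CSV")
  for (cc in setdiff(.SPECIMEN_COLS, c("species", "sex"))) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- !is.na(df[[cc]]) & df[[cc]] <= 0
    if (any(bad)) {
      stop("non-positive measurement(s) in column ", cc)
    }
  }
  message(sprintf("read %d specimens of %d species from %s",
                  nrow(df), length(unique(df$species)), basename(path)))
  df
}

#' Read a behaviour record CSV
#'
#' Expected columns: `species, max_breeding_pairs, cavity_override (0/1),
#' foraging_category` (one of `"solitary"`, `"pairs"`, `"groups"`). Missing
#' entries are allowed (species then drop out of the corresponding analysis).
#'
#' @param path CSV file path.
#' @return data.frame of behaviour records, one row per species.
#' @export
read_behavior_csv <- function(path) {
  if (!file.exists(path)) stop("behavior file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty behavior file: ", path)
  missing_cols <- setdiff(.BEHAVIOR_COLS, names(df))
  if (length(missing_cols)) {
    stop("behavior CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$species <- trimws(as.character(df$species))
  if (anyDuplicated(df$species)) {
    stop("duplicate species in behavior CSV: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  }
  df$max_breeding_pairs <- suppressWarnings(as.numeric(df$max_breeding_pairs))
  df$cavity_override <- suppressWarnings(as.integer(df$cavity_override))
  df$cavity_override[is.na(df$cavity_override)] <- 0L
  df$foraging_category <- trimws(as.character(df$foraging_category))
  df$foraging_category[!nzchar(df$foraging_category)] <- NA_character_
  df
}

#' Read a species-level trait table CSV
#'
#' First column is the taxon label; remaining columns are numeric traits.
#' Non-numeric cells become missing; duplicate taxa are an error; every row
#' must retain at least one value.
#'
#' @param path CSV file path.
#' @return numeric matrix, taxa as rownames.
#' @export
read_trait_csv <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty trait file: ", path)
  taxa <- trimws(as.character(df[[1L]]))
  if (anyDuplicated(taxa)) {
    stop("duplicate taxa in trait CSV: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  m <- as.matrix(as.data.frame(lapply(df[-1L],
                                      function(x) suppressWarnings(as.numeric(x)))))
  rownames(m) <- taxa
  all_na <- rowSums(!is.na(m)) == 0L
  if (any(all_na)) {
    stop("taxa with no trait values: ", paste(taxa[all_na], collapse = ", "))
  }
  message(sprintf("read trait table: %d taxa x %d traits", nrow(m), ncol(m)))
  m
}

#' Per-specimen trait derivation (side averaging and tail-fork depth)
#'
#' Bilateral traits are averaged over the sides present (a single present side
#' passes through; both sides missing yields a missing trait while the
#' specimen remains usable for its other traits). Tail-fork depth is the mean
#' outer tail length minus the middle tail length, computed within specimen;
#' it may legitimately be zero or negative.
#'
#' @param specimens data.frame from [read_specimen_csv()].
#' @return data.frame with columns `species`, `sex`, and the six traits of
#'   [trait_names()] in mm.
#' @export
specimen_traits <- function(specimens) {
  side_mean <- function(L, R) {
    m <- rowMeans(cbind(L, R), na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }
  outer <- side_mean(specimens$outer_tail_L, specimens$outer_tail_R)
  data.frame(
    species     = specimens$species,
    sex         = if ("sex" %in% names(specimens)) specimens$sex else NA,
    wing        = specimens$wing,
    outer_tail  = outer,
    tail_fork   = outer - specimens$middle_tail,
    tarsus      = side_mean(specimens$tarsus_L, specimens$tarsus_R),
    bill_length = specimens$bill_length,
    bill_width  = specimens$bill_width,
    stringsAsFactors = FALSE
  )
}

#' Species-level trait means from specimen traits
#'
#' Per species and trait, the mean over the specimens with that trait present;
#' sexes pooled with equal weight per specimen by default. With
#' `balance_sexes = TRUE` the species value is instead the unweighted mean of
#' the per-sex means (specimens of unknown sex then form their own class).
#'
#' @param spec_traits data.frame from [specimen_traits()].
#' @param balance_sexes see above; default `FALSE`.
#' @return numeric matrix taxa x traits (mm) with attribute `"n_specimens"`
#'   (per-cell specimen counts). Cells with no usable specimens are missing
#'   and warned about.
#' @export
species_means <- function(spec_traits, balance_sexes = FALSE) {
  traits <- trait_names()
  sp <- sort(unique(spec_traits$species))
  out <- matrix(NA_real_, length(sp), length(traits),
                dimnames = list(sp, traits))
  cnt <- matrix(0L, length(sp), length(traits), dimnames = list(sp, traits))
  for (i in seq_along(sp)) {
    rows <- spec_traits[spec_traits$species == sp[i], , drop = FALSE]
    for (j in seq_along(traits)) {
      v <- rows[[traits[j]]]
      ok <- !is.na(v)
      cnt[i, j] <- sum(ok)
      if (!any(ok)) next
      if (balance_sexes) {
        sex <- as.character(rows$sex)
        sex[is.na(sex) | !nzchar(sex)] <- "unknown"
        out[i, j] <- mean(tapply(v[ok], sex[ok], mean))
      } else {
        out[i, j] <- mean(v[ok])
      }
    }
  }
  empty <- which(cnt == 0L, arr.ind = TRUE)
  if (nrow(empty)) {
    warning("no usable specimens for ", nrow(empty),
            " species x trait cell(s), left missing")
  }
  attr(out, "n_specimens") <- cnt
  out
}

#' Scale traits by tarsus length to control for body size
#'
#' Every trait except tarsus is divided by the species' tarsus length; the
#' tarsus column is kept in mm. Species with a missing or non-positive tarsus
#' are dropped with a warning.
#'
#' @param tab taxa x traits matrix in mm containing a `"tarsus"` column.
#' @return matrix of tarsus-relative ratios (tarsus still in mm).
#' @export
scale_by_tarsus <- function(tab) {
  if (!"tarsus" %in% colnames(tab)) stop("no \"tarsus\" column")
  tarsus <- tab[, "tarsus"]
  bad <- is.na(tarsus) | tarsus <= 0
  if (any(bad)) {
    warning("dropping species with missing/non-positive tarsus: ",
            paste(rownames(tab)[bad], collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
    tarsus <- tarsus[!bad]
  }
  out <- sweep(tab, 1L, tarsus, "/")
  out[, "tarsus"] <- tab[, "tarsus"]
  out
}

.binary_character <- function(states, state_names) {
  states <- states[!is.na(states)]
  storage.mode(states) <- "integer"
  attr(states, "state_names") <- state_names
  states
}

#' Classify breeding behaviour from maximum breeding group size
#'
#' A species is social (state 1) when it has been documented nesting in groups
#' of five or more pairs. The cavity-reuse override handles taxa that reach
#' such counts only because existing cavities happen to be adjacent, with no
#' social cohesion; overridden species are classified solitary regardless of
#' group size. Species with unknown group size are excluded.
#'
#' @param max_pairs numeric vector of maximum reported breeding group sizes
#'   (pairs), names = species.
#' @param override logical/0-1 vector (recycled) flagging cavity-reuse taxa.
#' @param species optional species labels (default `names(max_pairs)`).
#' @return named integer vector of 0 (solitary) / 1 (social) with attribute
#'   `"state_names"`; species with missing sizes are dropped.
#' @export
classify_breeding <- function(max_pairs, override = FALSE, species = NULL) {
  if (is.null(species)) species <- names(max_pairs)
  if (is.null(species)) stop("species labels required")
  override <- rep_len(as.logical(override), length(max_pairs))
  known <- !is.na(max_pairs)
  if (any(max_pairs[known] < 1)) stop("breeding group size must be >= 1 pair")
  st <- ifelse(max_pairs >= 5 & !override, 1L, 0L)
  names(st) <- species
  .binary_character(st, c("solitary", "social"))
}

#' Classify foraging behaviour from a coded literature category
#'
#' Species observed to forage solitarily or as breeding pairs only fall in the
#' pairs category (state 0); species observed foraging in groups beyond the
#' pair are groups (state 1). Free-text descriptions must be pre-coded into
#' these categories upstream.
#'
#' @param category character vector in `{"solitary","pairs","groups"}` (NA
#'   allowed: species excluded), names = species.
#' @param species optional species labels (default `names(category)`).
#' @return named integer vector of 0 (pairs) / 1 (groups) with attribute
#'   `"state_names"`.
#' @export
classify_foraging <- function(category, species = NULL) {
  if (is.null(species)) species <- names(category)
  if (is.null(species)) stop("species labels required")
  category <- trimws(tolower(as.character(category)))
  category[!nzchar(category)] <- NA_character_
  bad <- !is.na(category) & !category %in% c("solitary", "pairs", "groups")
  if (any(bad)) {
    stop("unknown foraging category: ",
         paste(unique(category[bad]), collapse = ", "))
  }
  st <- ifelse(is.na(category), NA_integer_,
               ifelse(category == "groups", 1L, 0L))
  names(st) <- species
  .binary_character(st, c("pairs", "groups"))
}

#' Both social characters from a behaviour table
#' @param behavior data.frame from [read_behavior_csv()].
#' @return list with elements `breeding` and `foraging` (binary characters).
#' @export
behavior_characters <- function(behavior) {
  list(
    breeding = classify_breeding(behavior$max_breeding_pairs,
                                 behavior$cavity_override,
                                 species = behavior$species),
    foraging = classify_foraging(behavior$foraging_category,
                                 species = behavior$species)
  )
}
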