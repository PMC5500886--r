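#' @useDynLib symbiodep, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats density median rnorm runif rbinom rexp var sd quantile setNames
#' @importFrom utils read.csv write.csv read.delim
NULL

# Controlled vocabularies for the symbiosis database.
MEASURE_TYPES <- c("fecundity", "size_mass", "developmental_time", "survival", "resistance")
TRANSMISSION_MODES <- c("vertical", "horizontal")
FUNCTION_TYPES <- c("nutritional", "defensive", "unknown")
LOCALIZATIONS <- c("intracellular", "extracellular")
OBLIGACY_TYPES <- c("obligate", "facultative")

# Canonical column order for observation tables (External Interfaces contract).
DB_COLUMNS <- c("study_id", "host_species", "symbiont_species",
                "fitness_with", "fitness_without", "measure_type", "sample_size",
                "transmission", "func", "localization", "obligacy",
                "genome_size", "age", "fitness_drop_pct")

RECORD_COLUMNS <- c("host_species", "symbiont_species", "transmission", "func",
                    "localization", "obligacy", "genome_size", "age",
                    "mean_fitness_drop", "n_observations")

fold_name <- function(x) tolower(trimws(x))

#' Standardized percentage drop in host fitness
#'
#' Computes the percentage change in host fitness caused by symbiont removal,
#' standardized across assays measured in different units:
#' \deqn{100 (w_{+} - w_{-}) / w_{+}}
#' where \eqn{w_{+}} is host fitness with the symbiont and \eqn{w_{-}} without
#' it. Positive values mean the host does worse without its symbiont (it is
#' dependent); negative values mean removal improved fitness. The drop is
#' bounded above by 100 (when \eqn{w_{-} \ge 0}) but unbounded below.
#'
#' @param fitness_with Host fitness with the symbiont present (must be > 0).
#' @param fitness_without Host fitness after symbiont removal (>= 0).
#' @return Numeric vector of percentage fitness drops.
#' @examples
#' compute_fitness_drop(10, 4.8)   # 52
#' compute_fitness_drop(10, 12)    # -20: removal helped
#' @export
compute_fitness_drop <- function(fitness_with, fitness_without) {
  if (any(!is.finite(fitness_with)) || any(!is.finite(fitness_without)))
    stop("fitness values must be finite")
  if (any(fitness_with <= 0))
    stop("fitness_with must be > 0: the percentage drop is undefined when ",
         "baseline fitness is zero")
  if (any(fitness_without < 0))
    stop("fitness_without must be >= 0")
  100 * (fitness_with - fitness_without) / fitness_with
}

check_enum <- function(values, allowed, column) {
  v <- fold_name(values)
  bad <- which(!(v %in% allowed))
  if (length(bad) > 0)
    stop(sprintf("invalid %s value '%s' in row %d (allowed: %s)",
                 column, values[bad[1]], bad[1], paste(allowed, collapse = ", ")))
  v
}

#' Load and validate a host-symbiont fitness database
#'
#' Reads a delimited text file (CSV or TSV) with one row per fitness-change
#' measurement, validates the controlled vocabularies, computes the
#' standardized percentage fitness drop for every row, and aggregates rows into
#' one record per unique host-symbiont pair.
#'
#' Direction handling: the drop formula presumes that a larger raw value means
#' a fitter host. For measure types where the opposite holds (by default only
#' \code{developmental_time}, where slower development is worse), the roles of
#' the with/without measurements are swapped before the formula is applied.
#'
#' @param path Path to a CSV (or TSV, by extension) file. Required columns:
#'   study_id, host_species, symbiont_species, fitness_with, fitness_without,
#'   measure_type, sample_size, transmission, func, localization, obligacy;
#'   optional: genome_size, age (empty cells = missing).
#' @param schema Optional named character vector mapping canonical column names
#'   to the file's column names, e.g. \code{c(func = "symbiont_function")}.
#' @param invert_measures Measure types whose raw scale is inverted (larger =
#'   worse) before standardization.
#' @return An object of class \code{symbiosis_data}: a list with
#'   \code{observations} (one row per measurement, with
#'   \code{fitness_drop_pct}) and \code{records} (one row per unique
#'   host-symbiont pair with aggregated genome size, age and mean drop).
#' @export
load_database <- function(path, schema = NULL,
                          invert_measures = "developmental_time") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, na.strings = c("", "NA"))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!(schema[[canon]] %in% names(raw)))
        stop("schema maps '", canon, "' to missing column '", schema[[canon]], "'")
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  required <- setdiff(DB_COLUMNS, c("genome_size", "age", "fitness_drop_pct"))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!("genome_size" %in% names(raw))) raw$genome_size <- NA_real_
  if (!("age" %in% names(raw))) raw$age <- NA_real_

  obs <- raw[, setdiff(DB_COLUMNS, "fitness_drop_pct")]
  obs$host_species <- trimws(obs$host_species)
  obs$symbiont_species <- trimws(obs$symbiont_species)
  obs$measure_type <- check_enum(obs$measure_type, MEASURE_TYPES, "measure_type")
  obs$transmission <- check_enum(obs$transmission, TRANSMISSION_MODES, "transmission")
  obs$func <- check_enum(obs$func, FUNCTION_TYPES, "func")
  obs$localization <- check_enum(obs$localization, LOCALIZATIONS, "localization")
  obs$obligacy <- check_enum(obs$obligacy, OBLIGACY_TYPES, "obligacy")

  if (any(is.na(obs$sample_size)))
    stop("missing sample_size in row ", which(is.na(obs$sample_size))[1])
  if (any(obs$sample_size < 1 | obs$sample_size != round(obs$sample_size)))
    stop("sample_size must be a positive integer (row ",
         which(obs$sample_size < 1 | obs$sample_size != round(obs$sample_size))[1], ")")

  bad <- obs$transmission == "horizontal" & obs$obligacy == "obligate"
  if (any(bad))
    stop("consistency error in row ", which(bad)[1],
         ": horizontally transmitted symbionts are facultative by definition")

  invert <- obs$measure_type %in% invert_measures
  w_plus <- ifelse(invert, obs$fitness_without, obs$fitness_with)
  w_minus <- ifelse(invert, obs$fitness_with, obs$fitness_without)
  obs$fitness_drop_pct <- compute_fitness_drop(w_plus, w_minus)

  out <- list(observations = obs, records = build_records(obs))
  class(out) <- "symbiosis_data"
  out
}

# One record per unique (host, symbiont) pair; genome size and age are the
# arithmetic mean over non-missing entries for that symbiont pair.
build_records <- function(obs) {
  if (nrow(obs) == 0) {
    rec <- as.data.frame(setNames(rep(list(character(0)), length(RECORD_COLUMNS)),
                                  RECORD_COLUMNS))
    return(rec)
  }
  key <- paste(fold_name(obs$host_species), fold_name(obs$symbiont_species), sep = "\r")
  idx <- split(seq_len(nrow(obs)), key)
  idx <- idx[order(vapply(idx, min, 1L))]  # first-appearance order
  rows <- lapply(idx, function(i) {
    sub <- obs[i, , drop = FALSE]
    for (col in c("transmission", "func", "localization", "obligacy")) {
      if (length(unique(sub[[col]])) > 1)
        stop("inconsistent ", col, " within pair (",
             sub$host_species[1], ", ", sub$symbiont_species[1], ")")
    }
    data.frame(
      host_species = sub$host_species[1],
      symbiont_species = sub$symbiont_species[1],
      transmission = sub$transmission[1],
      func = sub$func[1],
      localization = sub$localization[1],
      obligacy = sub$obligacy[1],
      genome_size = if (all(is.na(sub$genome_size))) NA_real_ else
        mean(sub$genome_size, na.rm = TRUE),
      age = if (all(is.na(sub$age))) NA_real_ else mean(sub$age, na.rm = TRUE),
      mean_fitness_drop = mean(sub$fitness_drop_pct),
      n_observations = nrow(sub),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.symbiosis_data <- function(x, ...) {
  cat("symbiosis_data:", nrow(x$observations), "fitness measurements,",
      nrow(x$records), "unique host-symbiont pairs,",
      length(unique(x$observations$study_id)), "studies\n")
  tab <- table(x$records$transmission)
  cat("  transmission:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-symbiosis mean fitness drop
#'
#' Aggregates observation-level drops to the unweighted arithmetic mean per
#' unique host-symbiont pair. Per-observation sample sizes do not weight this
#' mean; they enter the models as measurement-error variances instead.
#'
#' @param observations Observation table (as in \code{load_database()$observations}).
#' @return data.frame with host_species, symbiont_species, mean_fitness_drop,
#'   n_observations; one row per unique pair.
#' @export
aggregate_by_symbiosis <- function(observations) {
  if (nrow(observations) == 0)
    return(data.frame(host_species = character(0), symbiont_species = character(0),
                      mean_fitness_drop = numeric(0), n_observations = integer(0)))
  rec <- build_records(observations)
  rec[, c("host_species", "symbiont_species", "mean_fitness_drop", "n_observations")]
}

#' Filter a symbiosis database
#'
#' Subsets observations by field values or by presence of optional fields, and
#' re-derives the per-pair records from the filtered observations.
#'
#' @param x A \code{symbiosis_data} object.
#' @param filters Named list. Names must be observation columns (values kept if
#'   in the supplied set) or one of \code{has_genome_size}/\code{has_age}
#'   (logical: require the field to be non-missing).
#' @return A filtered \code{symbiosis_data} object.
#' @export
subset_database <- function(x, filters = list()) {
  stopifnot(inherits(x, "symbiosis_data"))
  obs <- x$observations
  keep <- rep(TRUE, nrow(obs))
  for (f in names(filters)) {
    if (f %in% c("has_genome_size", "has_age")) {
      col <- sub("^has_", "", f)
      if (isTRUE(filters[[f]])) keep <- keep & !is.na(obs[[col]])
    } else if (f %in% names(obs)) {
      keep <- keep & (obs[[f]] %in% filters[[f]])
    } else {
      stop("unknown filter field: ", f)
    }
  }
  out <- list(observations = obs[keep, , drop = FALSE],
              records = build_records(obs[keep, , drop = FALSE]))
  rownames(out$observations) <- NULL
  class(out) <- "symbiosis_data"
  out
}

#' Reclassify the transmission mode of named symbionts
#'
#' Used for sensitivity analyses in which symbionts with a possible biparental
#' transmission component are reassigned to the horizontal class. Obligacy
#' consistency is re-checked: an obligate symbiont cannot become horizontal.
#'
#' @param x A \code{symbiosis_data} object.
#' @param taxa Character vector of symbiont species names (matched after
#'   whitespace trimming and case folding).
#' @param new_mode \code{"vertical"} or \code{"horizontal"}.
#' @return The modified \code{symbiosis_data} object.
#' @export
reclassify_transmission <- function(x, taxa, new_mode = "horizontal") {
  stopifnot(inherits(x, "symbiosis_data"))
  new_mode <- match.arg(new_mode, TRANSMISSION_MODES)
  if (length(taxa) == 0) return(x)
  obs <- x$observations
  present <- fold_name(taxa) %in% fold_name(obs$symbiont_species)
  if (any(!present))
    warning("taxa not found in database (ignored): ",
            paste(taxa[!present], collapse = ", "))
  hit <- fold_name(obs$symbiont_species) %in% fold_name(taxa)
  if (new_mode == "horizontal" && any(hit & obs$obligacy == "obligate"))
    stop("consistency error: cannot reclassify obligate symbiont(s) as horizontal: ",
         paste(unique(obs$symbiont_species[hit & obs$obligacy == "obligate"]),
               collapse = ", "))
  obs$transmission[hit] <- new_mode
  out <- list(observations = obs, records = build_records(obs))
  class(out) <- "symbiosis_data"
  out
}

#' Write a symbiosis database to normalized CSV
#'
#' Writes the observation table (and optionally the per-pair record table) with
#' the documented fixed column order, so that \code{load_database()} round-trips.
#'
#' @param x A \code{symbiosis_data} object.
#' @param path Output CSV path for observations.
#' @param records_path Optional CSV path for the aggregated records.
#' @return \code{path}, invisibly.
#' @export
write_database <- function(x, path, records_path = NULL) {
  stopifnot(inherits(x, "symbiosis_data"))
  write.csv(x$observations[, DB_COLUMNS], path, row.names = FALSE, na = "")
  if (!is.null(records_path))
    write.csv(x$records[, RECORD_COLUMNS], records_path, row.names = FALSE, na = "")
  invisible(path)
}
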