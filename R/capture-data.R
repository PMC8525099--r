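#' Age classes used by the survival submodels
#'
#' Survival is structured by seven age classes: cubs of the year (A0),
#' yearlings (A1), first-year-independent two-year-olds (A2), subadults aged
#' 3-4 (A3_4), adults aged 5-19 (A5_19), old adults aged 20+ (A20plus), and
#' bears of unknown age (mostly biopsy-identified), whose survival is a
#' mixture over the three adult classes.  Classes are indexed internally
#' 1..7 in the order above.
#'
#' @param age Integer vector of ages in years; `NA` means unknown.
#' @return Character vector of age-class labels.
#' @examples
#' age_class(c(0, 1, 4, 19, 20, NA))
#' @export
age_class <- function(age) {
  if (any(age < 0, na.rm = TRUE)) stop("ages must be non-negative")
  labs <- mscjs_age_classes()
  labs[age_class_index(age)]
}

mscjs_age_classes <- function() {
  c("A0", "A1", "A2", "A3_4", "A5_19", "A20plus", "Unknown")
}

# 1..7 index into the class order above; NA age -> 7 (Unknown)
age_class_index <- function(age) {
  idx <- rep.int(7L, length(age))
  known <- !is.na(age)
  a <- age[known]
  idx[known] <- ifelse(a >= 20, 6L,
                ifelse(a >= 5, 5L,
                ifelse(a >= 3, 4L, a + 1L)))
  idx
}

#' Assemble a multistate mark-recapture data set
#'
#' Bundles and validates the three data components the models consume:
#' per-observation encounter records of physically captured or
#' biopsy-identified bears (states 1-4 only; a bear alive in state 5,
#' "Elsewhere", is unobservable), annual state assignments for
#' telemetry-instrumented bears (states 1-5; these bears are known alive over
#' their span and inform only the state-transition probabilities), and the
#' state-by-year search-effort table.  Also derives the per-bear quantities
#' the likelihood needs: first observation, sex, age class by year (unknown
#' age stays unknown), and the encounter matrix.
#'
#' @param observations data.frame with columns `bear_id`, `year`, `sex`
#'   ("F"/"M"), `age` (integer age at that observation, `NA` if unknown),
#'   `type` ("C" capture / "B" biopsy), `state` (1..4).  At most one
#'   observation per bear-year (paint-marking prevented within-season
#'   recapture).
#' @param telemetry Optional data.frame with columns `bear_id`, `year`,
#'   `state` (1..5); each bear needs assignments in at least two years.
#' @param effort Optional [effort_table()] (required by the
#'   State + Distance recapture submodel).
#' @param years Integer vector of consecutive study years (the annual
#'   occasions); default spans the years present in the data.
#' @return An object of class `mscjs_data`.
#' @export
mscjs_data <- function(observations, telemetry = NULL, effort = NULL,
                       years = NULL) {
  obs <- as.data.frame(observations)
  need <- c("bear_id", "year", "sex", "age", "type", "state")
  if (!all(need %in% names(obs)))
    stop("observations must have columns ", paste(need, collapse = ", "))
  if (is.null(years)) {
    yr <- obs$year
    if (!is.null(telemetry)) yr <- c(yr, telemetry$year)
    years <- seq(min(yr), max(yr))
  }
  years <- as.integer(years)
  stopifnot(all(diff(years) == 1L), length(years) >= 2L)
  if (!all(obs$year %in% years)) stop("observation years outside study years")
  if (!all(obs$state %in% 1:4)) stop("observed states must be in 1..4")
  if (!all(obs$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!all(obs$type %in% c("C", "B"))) stop("type must be 'C' or 'B'")
  if (anyDuplicated(obs[c("bear_id", "year")]))
    stop("at most one observation per bear per year")
  if (any(tapply(obs$sex, obs$bear_id, function(s) length(unique(s))) > 1L))
    stop("inconsistent sex within bear_id")

  obs <- obs[order(obs$bear_id, obs$year), , drop = FALSE]
  first_row <- !duplicated(obs$bear_id)
  bears <- data.frame(bear_id = obs$bear_id[first_row],
                      sex = obs$sex[first_row],
                      first_year = obs$year[first_row],
                      age_at_first = obs$age[first_row],
                      stringsAsFactors = FALSE)
  n <- nrow(bears)
  K <- length(years)

  # encounter matrix: 0 = not observed, 1..4 = observed state; years before
  # first observation are structurally ignored by the conditional likelihood
  enc <- matrix(0L, n, K, dimnames = list(bears$bear_id, years))
  enc[cbind(match(obs$bear_id, bears$bear_id), match(obs$year, years))] <-
    as.integer(obs$state)

  # age-class index per bear-year (class occupied DURING year k, governing
  # survival k -> k+1); advancement is deterministic by calendar year
  offset <- matrix(seq_len(K), n, K, byrow = TRUE) -
    match(bears$first_year, years)
  ages <- bears$age_at_first + offset
  ages[!is.na(ages) & ages < 0] <- 0L  # pre-entry years, never used
  acl <- matrix(age_class_index(as.vector(ages)), n, K)

  tel <- NULL
  if (!is.null(telemetry) && nrow(telemetry) > 0L) {
    tel <- as.data.frame(telemetry)
    if (!all(c("bear_id", "year", "state") %in% names(tel)))
      stop("telemetry must have columns bear_id, year, state")
    if (!all(tel$state %in% 1:5)) stop("telemetry states must be in 1..5")
    if (!all(tel$year %in% years)) stop("telemetry years outside study years")
    if (anyDuplicated(tel[c("bear_id", "year")]))
      stop("at most one telemetry state per bear per year")
    if (any(table(tel$bear_id) < 2L))
      stop("each telemetry bear needs state assignments in >= 2 years")
    tel <- tel[order(tel$bear_id, tel$year), , drop = FALSE]
  }

  # sufficient statistics for the telemetry likelihood: counts of observed
  # (from, to, gap) state pairs between successive assignments of each bear
  tel_trans <- NULL
  if (!is.null(tel)) {
    i <- seq_len(nrow(tel) - 1L)
    same <- tel$bear_id[i] == tel$bear_id[i + 1L]
    tt <- data.frame(from = tel$state[i][same], to = tel$state[i + 1L][same],
                     gap = tel$year[i + 1L][same] - tel$year[i][same])
    agg <- stats::aggregate(list(count = rep(1L, nrow(tt))),
                            by = tt, FUN = sum)
    tel_trans <- agg
  }

  first_idx <- match(bears$first_year, years)
  sex_idx <- ifelse(bears$sex == "F", 2L, 1L)

  # deduplicate likelihood-equivalent bear profiles (same sex, entry, age
  # classes, and encounter row); the sampler sums weighted profile
  # log-likelihoods instead of iterating all bears
  acl_canon <- acl
  pre <- col(acl) < first_idx
  acl_canon[pre] <- 1L
  key <- paste(first_idx, sex_idx,
               apply(enc, 1L, paste, collapse = ","),
               apply(acl_canon, 1L, paste, collapse = ","))
  uniq <- which(!duplicated(key))
  map <- match(key, key[uniq])
  dedup <- list(enc_t = t(enc[uniq, , drop = FALSE]),
                acl_t = t(acl_canon[uniq, , drop = FALSE]),
                first = first_idx[uniq], sex = sex_idx[uniq],
                weight = as.numeric(tabulate(map, nbins = length(uniq))))

  structure(list(observations = obs, telemetry = tel, tel_trans = tel_trans,
                 effort = effort,
                 years = years, bears = bears, encounter = enc,
                 age_class_idx = acl,
                 first_idx = first_idx,
                 sex_idx = sex_idx,
                 dedup = dedup),
            class = "mscjs_data")
}

#' @export
print.mscjs_data <- function(x, ...) {
  cat("Multistate mark-recapture data set\n")
  cat(sprintf("  %d observations of %d bears over %d occasions (%d-%d)\n",
              nrow(x$observations), nrow(x$bears), length(x$years),
              min(x$years), max(x$years)))
  if (!is.null(x$telemetry))
    cat(sprintf("  %d annual state assignments of %d telemetry bears\n",
                nrow(x$telemetry), length(unique(x$telemetry$bear_id))))
  cat(sprintf("  effort table: %s\n",
              if (is.null(x$effort)) "none" else "present"))
  invisible(x)
}

#' Annual observation and recapture summary
#'
#' Tabulates, by year and observation type, the number of bears observed (C)
#' and how many of those were recaptures (R) -- bears first observed in an
#' earlier year.  Totals satisfy individuals = observations - recaptures.
#'
#' @param data An [mscjs_data()] object, or an observation data.frame in the
#'   same schema.
#' @return A list with `by_year` (data.frame: year, capture_C, capture_R,
#'   biopsy_C, biopsy_R, total_C, total_R), and scalar `observations`,
#'   `recaptures`, `individuals`, `biopsy_identifications`.
#' @export
summarize_observations <- function(data) {
  obs <- if (inherits(data, "mscjs_data")) data$observations else
           as.data.frame(data)
  obs <- obs[order(obs$bear_id, obs$year), , drop = FALSE]
  first_year <- stats::ave(obs$year, obs$bear_id, FUN = min)
  recap <- obs$year > first_year
  years <- sort(unique(obs$year))
  cnt <- function(sel) {
    c_ <- as.vector(table(factor(obs$year[sel], levels = years)))
    r_ <- as.vector(table(factor(obs$year[sel & recap], levels = years)))
    list(C = c_, R = r_)
  }
  cap <- cnt(obs$type == "C")
  bio <- cnt(obs$type == "B")
  by_year <- data.frame(year = years,
                        capture_C = cap$C, capture_R = cap$R,
                        biopsy_C = bio$C, biopsy_R = bio$R,
                        total_C = cap$C + bio$C, total_R = cap$R + bio$R)
  list(by_year = by_year,
       observations = nrow(obs),
       recaptures = sum(recap),
       individuals = length(unique(obs$bear_id)),
       biopsy_identifications = sum(obs$type == "B"))
}

#' State occupancy counts and known transitions
#'
#' Counts annual state assignments per spatial state over the combined
#' mark-recapture and telemetry data, and the number of known transitions:
#' instances in which a bear has state assignments in consecutive years, so
#' the transition is observed without error.
#'
#' @param data An [mscjs_data()] object, or a list with elements
#'   `observations` and (optionally) `telemetry`.
#' @return A list with `state_counts` (named integer vector over states 1-5),
#'   `total`, and `known_transitions`.
#' @export
tabulate_states <- function(data) {
  obs <- data$observations
  tel <- data$telemetry
  comb <- data.frame(bear_id = obs$bear_id, year = obs$year,
                     state = obs$state, stringsAsFactors = FALSE)
  if (!is.null(tel) && nrow(tel) > 0L) {
    comb <- rbind(comb, data.frame(bear_id = paste0("tel:", tel$bear_id),
                                   year = tel$year, state = tel$state,
                                   stringsAsFactors = FALSE))
  }
  counts <- tabulate(comb$state, nbins = 5L)
  names(counts) <- 1:5
  comb <- comb[order(comb$bear_id, comb$year), , drop = FALSE]
  same <- comb$bear_id[-1L] == comb$bear_id[-nrow(comb)]
  consec <- comb$year[-1L] - comb$year[-nrow(comb)] == 1L
  list(state_counts = counts, total = sum(counts),
       known_transitions = if (nrow(comb) > 1L) sum(same & consec) else 0L)
}

#' Read and write the observation / telemetry CSV schemas
#'
#' Observation CSV columns: `bear_id, year, sex, age, type, state` (age empty
#' for unknown).  Telemetry CSV columns: `bear_id, year, state`.  UTF-8 with
#' a header row.
#'
#' @param path File path.
#' @return A data.frame in the corresponding schema.
#' @rdname capture_io
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(bear_id = "character",
                                             sex = "character",
                                             type = "character"))
  stopifnot(all(c("bear_id", "year", "sex", "age", "type", "state") %in%
                  names(df)))
  df$year <- as.integer(df$year)
  df$age <- as.integer(df$age)
  df$state <- as.integer(df$state)
  df
}

#' @param observations,telemetry Data frames in the schemas above.
#' @rdname capture_io
#' @export
write_observations_csv <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname capture_io
#' @export
read_telemetry_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(bear_id = "character"))
  stopifnot(all(c("bear_id", "year", "state") %in% names(df)))
  df$year <- as.integer(df$year)
  df$state <- as.integer(df$state)
  df
}

#' @rdname capture_io
#' @export
write_telemetry_csv <- function(telemetry, path) {
  utils::write.csv(telemetry, path, row.names = FALSE, na = "")
  invisible(path)
}
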