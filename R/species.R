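#' Synthetic circumpolar species-trait table
#'
#' Builds a trait table whose marginal counts match the published tallies
#' for the circumpolar (CAFF-style) breeding-bird list: 449 species that
#' breed or have bred in the Arctic, 359 of them with a breeding-range
#' overlap of at least 5%, 316 of those migratory or partially migratory,
#' 29 pelagic and 37 coastal-marine winterers among the migrants, and 24 of
#' those 66 with documented polar-night activity. Species identities are
#' synthetic placeholders; only the marginals are meaningful.
#'
#' @param n_total,n_overlap,n_migrant,n_pelagic,n_coastal,n_polar_night
#'   marginal counts to encode.
#' @return data frame with columns `species_id, family, breeds_arctic,
#'   arctic_overlap_pct, migratory_status, winter_habitat, polar_night`.
#' @export
synthetic_species_table <- function(n_total = 449L, n_overlap = 359L,
                                    n_migrant = 316L, n_pelagic = 29L,
                                    n_coastal = 37L, n_polar_night = 24L) {
  stopifnot(n_overlap <= n_total, n_migrant <= n_overlap,
            n_pelagic + n_coastal <= n_migrant,
            n_polar_night <= n_pelagic + n_coastal)
  id <- sprintf("sp%03d", seq_len(n_total))
  fam <- sprintf("fam%02d", (seq_len(n_total) - 1L) %% 44L + 1L)
  overlap <- c(seq(5, 100, length.out = n_overlap),        # inclusive >= 5
               seq(0, 4.9, length.out = n_total - n_overlap))
  status <- rep("resident", n_total)
  status[seq_len(n_migrant)] <- rep(c("migrant", "partial_migrant"),
                                    length.out = n_migrant)
  habitat <- rep("other", n_total)
  habitat[seq_len(n_pelagic)] <- "pelagic"
  habitat[n_pelagic + seq_len(n_coastal)] <- "coastal_marine"
  # a couple of non-migratory pelagic species: already resident, they stay so
  res_idx <- which(status == "resident")
  if (length(res_idx) >= 2L) habitat[res_idx[1:2]] <- "pelagic"
  polar <- rep(FALSE, n_total)
  marine_winter <- which(status != "resident" &
                           habitat %in% c("pelagic", "coastal_marine"))
  polar[marine_winter[seq_len(n_polar_night)]] <- TRUE
  data.frame(species_id = id, family = fam, breeds_arctic = TRUE,
             arctic_overlap_pct = round(overlap, 2),
             migratory_status = status, winter_habitat = habitat,
             polar_night = polar)
}

#' Filter breeders by Arctic range overlap
#'
#' Keeps species that breed in the Arctic and whose breeding range overlaps
#' the Arctic by at least `min_overlap` percent (inclusive).
#'
#' @param table species-trait data frame (see [synthetic_species_table()]).
#' @param min_overlap minimum overlap in percent (default 5).
#' @return the retained subset, with attributes `n`, `n_input` and `pct`
#'   (share of the input, in percent).
#' @export
filter_arctic_breeders <- function(table, min_overlap = 5) {
  if (nrow(table) == 0L) stop("empty species table")
  out <- table[table$breeds_arctic & table$arctic_overlap_pct >= min_overlap, ]
  attr(out, "n") <- nrow(out)
  attr(out, "n_input") <- nrow(table)
  attr(out, "pct") <- 100 * nrow(out) / nrow(table)
  out
}

#' Classify migratory-strategy candidates
#'
#' From the arctic-breeding subset, derives: `transarctic` — migrants or
#' partial migrants with a primarily pelagic winter habitat; `marine_winter`
#' — migrants or partial migrants wintering in pelagic or coastal-marine
#' habitat; `resident_candidates` — marine-winter species with documented
#' polar-night activity. Species already resident are assumed to remain so
#' and are excluded from all three lists.
#'
#' @param subset output of [filter_arctic_breeders()].
#' @return list of three data frames.
#' @export
classify_candidates <- function(subset) {
  known <- c("pelagic", "coastal_marine", "other")
  bad <- setdiff(unique(subset$winter_habitat), known)
  if (length(bad)) stop("unknown winter habitat class: ",
                        paste(bad, collapse = ", "))
  mig <- subset$migratory_status %in% c("migrant", "partial_migrant")
  transarctic <- subset[mig & subset$winter_habitat == "pelagic", ]
  marine_winter <- subset[mig & subset$winter_habitat %in%
                            c("pelagic", "coastal_marine"), ]
  resident_candidates <- marine_winter[marine_winter$polar_night, ]
  list(transarctic = transarctic, marine_winter = marine_winter,
       resident_candidates = resident_candidates)
}

#' Run the full screening cascade and tally each stage
#'
#' Applies [filter_arctic_breeders()] then [classify_candidates()] and
#' reports per-stage counts with percentages: overlap and migrant shares are
#' relative to the previous stage; the pelagic (transarctic-candidate) share
#' is relative to all arctic breeders.
#'
#' @param table species-trait data frame.
#' @param min_overlap overlap threshold in percent.
#' @return list with `stages` (data frame: stage, n, denominator, pct) and
#'   the three candidate lists.
#' @export
screen_species <- function(table, min_overlap = 5) {
  breeders <- table[table$breeds_arctic, ]
  kept <- filter_arctic_breeders(breeders, min_overlap)
  cls <- classify_candidates(kept)
  pct <- function(n, d) {
    if (any(d == 0)) stop("zero denominator")
    100 * n / d
  }
  stages <- data.frame(
    stage = c("arctic_breeders", "overlap_ge_threshold", "migrants",
              "pelagic_winter", "coastal_marine_winter", "marine_winter",
              "polar_night_residents"),
    n = c(nrow(breeders), nrow(kept),
          sum(kept$migratory_status %in% c("migrant", "partial_migrant")),
          nrow(cls$transarctic),
          nrow(cls$marine_winter) - nrow(cls$transarctic),
          nrow(cls$marine_winter), nrow(cls$resident_candidates)))
  stages$denominator <- c(nrow(breeders), nrow(breeders), nrow(kept),
                          nrow(breeders), nrow(breeders), stages$n[3],
                          stages$n[6])
  stages$pct <- pct(stages$n, stages$denominator)
  c(list(stages = stages), cls)
}

#' Read a species-trait table from CSV
#'
#' @param path CSV path with the documented header (see
#'   [synthetic_species_table()] for the columns).
#' @return data frame.
#' @export
read_species_csv <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "breeds_arctic", "arctic_overlap_pct",
            "migratory_status", "winter_habitat", "polar_night")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tb$breeds_arctic <- as.logical(tb$breeds_arctic)
  tb$polar_night <- as.logical(tb$polar_night)
  tb
}

#' Write a screening report as JSON
#'
#' @param screen output of [screen_species()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(screen, path) {
  rep <- list(stages = screen$stages,
              transarctic_candidates = screen$transarctic$species_id,
              resident_candidates = screen$resident_candidates$species_id)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
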