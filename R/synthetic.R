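# Deterministic synthetic occurrence data: toy reference geography and
# taxonomy, plus a seeded generator that injects quality defects at
# controlled rates and records per-record ground truth by construction,
# independently of the mechanisms under test.

#' Defect rates for the synthetic generator
#'
#' Each rate is an independent per-record probability. Coordinate defects
#' are mutually exclusive by a fixed precedence (missing over non-numeric
#' over out-of-range over wrong-country) so that ground-truth classes are
#' disjoint and counts unambiguous.
#'
#' @param p_missing_coord probability both coordinates are blanked.
#' @param p_nonnumeric_coord probability the latitude gets a comma-decimal
#'   (non-numeric) value.
#' @param p_out_of_range probability the latitude is pushed beyond 90.
#' @param p_wrong_country probability the country label is swapped to a
#'   different (distant) toy country.
#' @param p_missing_taxon_ranks probability genus and family are blanked.
#' @param p_misspelled_name probability the scientific name gets a
#'   one-character typo.
#' @return a `dq_defect_rates` object.
#' @export
defect_rates <- function(p_missing_coord = 0, p_nonnumeric_coord = 0,
                         p_out_of_range = 0, p_wrong_country = 0,
                         p_missing_taxon_ranks = 0, p_misspelled_name = 0) {
  r <- list(p_missing_coord = p_missing_coord,
            p_nonnumeric_coord = p_nonnumeric_coord,
            p_out_of_range = p_out_of_range,
            p_wrong_country = p_wrong_country,
            p_missing_taxon_ranks = p_missing_taxon_ranks,
            p_misspelled_name = p_misspelled_name)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("defect rate ", nm, " must be a probability in [0, 1]",
           call. = FALSE)
  }
  structure(r, class = "dq_defect_rates")
}

TOY_COUNTRIES <- list(
  Atlantis = c(lon0 = 0, lon1 = 10, lat0 = 0, lat1 = 10),
  Borduria = c(lon0 = 20, lon1 = 30, lat0 = 0, lat1 = 10),
  Syldavia = c(lon0 = 0, lon1 = 10, lat0 = 20, lat1 = 30))

square_ring <- function(b) {
  rbind(c(b[["lon0"]], b[["lat0"]]), c(b[["lon1"]], b[["lat0"]]),
        c(b[["lon1"]], b[["lat1"]]), c(b[["lon0"]], b[["lat1"]]),
        c(b[["lon0"]], b[["lat0"]]))
}

# coarse Brazil outline (decimal degrees, lon/lat) — synthetic stand-in for
# an administrative boundary, adequate for point-radius checks at the
# fixture scale.
brazil_ring <- function() {
  rbind(c(-74, -7), c(-70, 2), c(-60, 5), c(-50, 4), c(-35, -8),
        c(-39, -18), c(-48, -28), c(-53, -34), c(-58, -30), c(-58, -20),
        c(-65, -22), c(-70, -15), c(-74, -7))
}

toy_taxonomy <- function() {
  data.frame(
    name = c("Animalia", "Arthropoda", "Insecta", "Hymenoptera", "Apidae",
             "Tetragonisca", "Tetragonisca angustula",
             "Apis", "Apis mellifera",
             "Plantae", "Tracheophyta", "Magnoliopsida", "Fabales",
             "Fabaceae", "Mimosa", "Mimosa pudica"),
    rank = c("kingdom", "phylum", "class", "order", "family",
             "genus", "species",
             "genus", "species",
             "kingdom", "phylum", "class", "order",
             "family", "genus", "species"),
    parent = c("", "Animalia", "Arthropoda", "Insecta", "Hymenoptera",
               "Apidae", "Tetragonisca",
               "Apidae", "Apis",
               "", "Plantae", "Tracheophyta", "Magnoliopsida",
               "Fabales", "Fabaceae", "Mimosa"),
    stringsAsFactors = FALSE)
}

toy_gazetteer <- function() {
  sites <- list()
  for (cn in names(TOY_COUNTRIES)) {
    b <- TOY_COUNTRIES[[cn]]
    # interior grid points, well away from the boundary
    xs <- seq(b[["lon0"]] + 2, b[["lon1"]] - 2, length.out = 3)
    ys <- c(b[["lat0"]] + 3, b[["lat1"]] - 3)
    k <- 0L
    for (y in ys) for (x in xs) {
      k <- k + 1L
      sites[[length(sites) + 1L]] <- data.frame(
        locality = sprintf("%s - site %d", cn, k),
        decimalLatitude = sprintf("%.4f", y),
        decimalLongitude = sprintf("%.4f", x),
        coordinateUncertaintyInMeters = "100",
        country = cn, stringsAsFactors = FALSE)
    }
  }
  sites[[length(sites) + 1L]] <- data.frame(
    locality = "Campinas, SP", decimalLatitude = "-22.9056",
    decimalLongitude = "-47.0608", coordinateUncertaintyInMeters = "5000",
    country = "Brazil", stringsAsFactors = FALSE)
  sites[[length(sites) + 1L]] <- data.frame(
    locality = "Brasilia, DF", decimalLatitude = "-15.8000",
    decimalLongitude = "-47.9000", coordinateUncertaintyInMeters = "5000",
    country = "Brazil", stringsAsFactors = FALSE)
  do.call(rbind, sites)
}

toy_accepted_names <- function() {
  base <- c("Tetragonisca angustula", "Apis mellifera", "Mimosa pudica")
  genera <- c("Melipona", "Bombus", "Trigona", "Scaptotrigona", "Frieseomelitta",
              "Partamona", "Plebeia", "Nannotrigona")
  epithets <- c("flavolineata", "quadrifasciata", "spinipes", "bipunctata",
                "varia", "remota")
  extra <- as.vector(outer(genera, epithets, paste))
  unique(c(base, extra))[1:50]
}

#' Toy reference data for tests and examples
#'
#' Three simple square countries (Atlantis, Borduria, Syldavia), a coarse
#' synthetic Brazil outline, a bee/plant taxonomy including the
#' *Tetragonisca angustula* lineage, a 20-entry gazetteer whose points lie
#' inside their countries, and a 50-name accepted list.
#'
#' @param seed kept for interface symmetry; the fixtures are fixed.
#' @return a [reference_data()].
#' @export
generate_reference_fixtures <- function(seed = 1L) {
  boundaries <- lapply(TOY_COUNTRIES, function(b) list(square_ring(b)))
  boundaries$Brazil <- list(brazil_ring())
  gaz <- toy_gazetteer()
  reference_data(
    boundaries = boundaries,
    taxonomy = toy_taxonomy(),
    gazetteer = gaz[, c("locality", "decimalLatitude", "decimalLongitude",
                        "coordinateUncertaintyInMeters")],
    accepted_names = toy_accepted_names())
}

#' Write reference fixtures to files
#'
#' Emits boundaries.geojson, taxonomy.csv, gazetteer.csv and
#' accepted_names.txt in the formats [load_reference_data()] reads.
#'
#' @param reference a [reference_data()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_reference_fixtures <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  features <- lapply(names(reference$boundaries), function(nm) {
    rings <- reference$boundaries[[nm]]
    list(type = "Feature", properties = list(name = nm),
         geometry = list(
           type = "MultiPolygon",
           coordinates = lapply(rings, function(ring)
             list(lapply(seq_len(nrow(ring)), function(i)
               c(ring[i, 1L], ring[i, 2L]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file.path(dir, "boundaries.geojson"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(reference$taxonomy, file.path(dir, "taxonomy.csv"),
                   row.names = FALSE)
  utils::write.csv(reference$gazetteer, file.path(dir, "gazetteer.csv"),
                   row.names = FALSE)
  writeLines(reference$accepted_names,
             file.path(dir, "accepted_names.txt"))
  invisible(dir)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic occurrence dataset with ground truth
#'
#' Draws n clean records over the toy countries' interiors (coordinates,
#' uncertainty, datum, a species with genus and family from the toy
#' taxonomy, a gazetteer locality, an event date), then injects defects per
#' the rates from one seeded pseudo-random stream consumed in fixed field
#' order: identical `(n, rates, seed)` give byte-identical output.
#' Coordinate defect classes follow the precedence missing > non-numeric >
#' out-of-range > wrong-country, so at most one applies per record.
#' Ground-truth flags are set by construction at generation time, not by
#' running any mechanism; counts are the realized (not expected) numbers.
#'
#' @param n number of records (>= 1).
#' @param rates a [defect_rates()].
#' @param seed integer seed.
#' @return list with `resource` (a dataset `dq_data_resource`) and `truth`
#'   (list of `flags`, a per-record logical data.frame with columns
#'   coord_complete, coord_conformant, coord_consistent, taxon_complete,
#'   name_exact, and `counts`, their column sums).
#' @export
generate_dataset <- function(n, rates = defect_rates(), seed = 1L) {
  stopifnot(n >= 1)
  if (!inherits(rates, "dq_defect_rates")) rates <- do.call(defect_rates, rates)
  species_pool <- c("Tetragonisca angustula", "Apis mellifera", "Mimosa pudica")
  tax <- toy_taxonomy()
  gaz <- toy_gazetteer()
  country_names <- names(TOY_COUNTRIES)

  with_seed(seed, {
    ci <- sample.int(length(country_names), n, replace = TRUE)
    u_lat <- stats::runif(n); u_lon <- stats::runif(n)
    unc <- as.character(sample(c(10L, 30L, 50L, 100L), n, replace = TRUE))
    si <- sample.int(length(species_pool), n, replace = TRUE)
    du <- matrix(stats::runif(n * 6L), nrow = n)   # defect draws, fixed order
    u_oor <- stats::runif(n)                       # out-of-range magnitude
  })

  bounds <- do.call(rbind, lapply(TOY_COUNTRIES, function(b) b))
  b <- bounds[ci, , drop = FALSE]
  # interior margin of 1 degree keeps clean points well inside the boundary
  lat <- b[, "lat0"] + 1 + u_lat * (b[, "lat1"] - b[, "lat0"] - 2)
  lon <- b[, "lon0"] + 1 + u_lon * (b[, "lon1"] - b[, "lon0"] - 2)
  lat_s <- sprintf("%.4f", lat); lon_s <- sprintf("%.4f", lon)
  country <- country_names[ci]
  species <- species_pool[si]
  genus <- vapply(species, function(s) strsplit(s, " ")[[1L]][1L],
                  character(1), USE.NAMES = FALSE)
  family <- vapply(genus, function(g) {
    tax$parent[match(g, tax$name)]
  }, character(1), USE.NAMES = FALSE)
  locality <- sprintf("%s - site 1", country)

  d_missing <- du[, 1L] < rates$p_missing_coord
  d_nonnum <- du[, 2L] < rates$p_nonnumeric_coord
  d_oor <- du[, 3L] < rates$p_out_of_range
  d_wrongc <- du[, 4L] < rates$p_wrong_country
  d_taxon <- du[, 5L] < rates$p_missing_taxon_ranks
  d_name <- du[, 6L] < rates$p_misspelled_name
  # precedence: at most one coordinate defect class per record
  apply_nonnum <- d_nonnum & !d_missing
  apply_oor <- d_oor & !d_missing & !apply_nonnum
  apply_wrongc <- d_wrongc & !d_missing & !apply_nonnum & !apply_oor

  lat_s[d_missing] <- ""; lon_s[d_missing] <- ""
  lat_s[apply_nonnum] <- sub("\\.", ",", lat_s[apply_nonnum])
  lat_s[apply_oor] <- sprintf("%.4f", 90.5 + 9 * u_oor[apply_oor])
  country[apply_wrongc] <- country_names[
    (ci[apply_wrongc] %% length(country_names)) + 1L]

  genus[d_taxon] <- ""; family[d_taxon] <- ""
  misspell <- function(s) {
    # swap the second character for a letter that differs
    ch <- substr(s, 2L, 2L)
    paste0(substr(s, 1L, 1L), if (ch == "x") "y" else "x",
           substr(s, 3L, nchar(s)))
  }
  species[d_name] <- vapply(species[d_name], misspell, character(1),
                            USE.NAMES = FALSE)

  records <- lapply(seq_len(n), function(i) c(
    occurrenceID = sprintf("occ-%06d", i),
    scientificName = species[[i]],
    genus = genus[[i]],
    family = family[[i]],
    decimalLatitude = lat_s[[i]],
    decimalLongitude = lon_s[[i]],
    coordinateUncertaintyInMeters = unc[[i]],
    geodeticDatum = "WGS84",
    country = country[[i]],
    locality = locality[[i]],
    eventDate = "2020-01-15"))

  flags <- data.frame(
    coord_complete = !d_missing,
    coord_conformant = !d_missing & !apply_nonnum & !apply_oor,
    coord_consistent = !d_missing & !apply_nonnum & !apply_oor & !apply_wrongc,
    taxon_complete = !d_taxon,
    name_exact = !d_name)
  list(resource = dq_dataset(records, id = sprintf("synthetic-%d", seed)),
       truth = list(flags = flags, counts = as.list(colSums(flags))))
}
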