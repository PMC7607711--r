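#' APOE diplotype from rs429358 and rs7412 genotypes
#'
#' The two sites define the common protein isoforms through their haplotypes:
#' e4 = (rs429358 C, rs7412 C), e3 = (rs429358 T, rs7412 C),
#' e2 = (rs429358 T, rs7412 T). Unphased two-site genotypes resolve to a
#' unique diplotype except the double heterozygote (C/T at both sites), which
#' is consistent with e2/e4 or e1/e3 and is assigned e2/e4 here (the rare e1
#' haplotype, rs429358 C with rs7412 T, is treated as absent).
#'
#' @param g429358,g7412 character genotypes like `"CT"` (two alleles from
#'   \{C, T\}, order irrelevant), vectorized.
#' @param individual_id optional IDs for the output (default sequence).
#' @return Tibble with `individual_id`, `diplotype`, `e4_count`, `one_e4`,
#'   `two_e4`, `call_flag` (`"ok"`, `"ambiguous_e2e4"` or `"invalid"`).
#'   Invalid/missing genotypes yield an NA call flagged `"invalid"`, never an
#'   error.
#' @export
#' @examples
#' call_diplotype(c("CC", "TT", "CT"), c("CC", "CC", "CT"))
call_diplotype <- function(g429358, g7412, individual_id = NULL) {
  n <- length(g429358)
  stopifnot(length(g7412) == n)
  individual_id <- individual_id %||% as.character(seq_len(n))
  norm <- function(g) {
    g <- toupper(as.character(g))
    a <- strsplit(g, "")
    ok <- !is.na(g) & nchar(g) == 2 &
      purrr::map_lgl(a, ~ all(.x %in% c("C", "T")))
    # count of C alleles; NA when invalid
    ifelse(ok, purrr::map_int(a, ~ sum(.x == "C")), NA_integer_)
  }
  c1 <- norm(g429358)  # C count at rs429358 (C is the e4-defining allele)
  c2 <- norm(g7412)    # C count at rs7412   (T is the e2-defining allele)
  key <- paste(c1, c2)
  # enumerate consistent phasings of (C-count429358, C-count7412); the
  # "2 1"/"1 1" cells are where phase matters: "1 1" is the e2/e4-vs-e1/e3
  # ambiguity, resolved as e2/e4; cells needing an e1 haplotype are invalid.
  map <- c(
    "0 0" = "e2/e2", "0 1" = "e2/e3", "0 2" = "e3/e3",
    "1 0" = "e1/e2", "1 1" = "e2/e4", "1 2" = "e3/e4",
    "2 0" = "e1/e1", "2 1" = "e1/e4", "2 2" = "e4/e4"
  )
  dip <- unname(map[key])
  flag <- rep("ok", n)
  flag[key == "1 1"] <- "ambiguous_e2e4"
  bad <- is.na(dip) | grepl("e1", dip)
  dip[bad] <- NA_character_
  flag[bad] <- "invalid"
  e4 <- ifelse(is.na(dip), NA_integer_,
               purrr::map_int(strsplit(dip, "/"), ~ sum(.x == "e4")))
  tibble(individual_id = individual_id, diplotype = dip,
         e4_count = e4,
         one_e4 = as.integer(e4 == 1L), two_e4 = as.integer(e4 == 2L),
         call_flag = flag)
}

#' APOE diplotype from imputed dosages
#'
#' Imputed allele dosages at the two sites are hard-called when they fall
#' within `band` of an integer (0, 1, 2) and then routed through
#' [call_diplotype()]; out-of-band dosages give a flagged no-call.
#'
#' @param d429358,d7412 numeric dosages in \[0, 2\] counting the C allele at
#'   each site.
#' @param band half-width of the rounding band around each integer
#'   (default 0.1).
#' @param individual_id optional IDs.
#' @return As [call_diplotype()]; no-calls carry `call_flag = "no_call"`.
#' @export
call_from_dosages <- function(d429358, d7412, band = 0.1, individual_id = NULL) {
  n <- length(d429358)
  stopifnot(length(d7412) == n, band > 0)
  individual_id <- individual_id %||% as.character(seq_len(n))
  hard <- function(d) {
    r <- round(d)
    ifelse(!is.na(d) & abs(d - r) <= band & r >= 0 & r <= 2, r, NA_real_)
  }
  h1 <- hard(d429358); h2 <- hard(d7412)
  gt <- function(h) c("TT", "CT", "CC")[h + 1]  # h = C-allele count
  out <- call_diplotype(gt(h1), gt(h2), individual_id = individual_id)
  nocall <- is.na(h1) | is.na(h2)
  out$call_flag[nocall] <- "no_call"
  out$diplotype[nocall] <- NA_character_
  out$e4_count[nocall] <- NA_integer_
  out$one_e4[nocall] <- NA_integer_
  out$two_e4[nocall] <- NA_integer_
  out
}

#' Call APOE status from a genotype matrix
#'
#' Extracts the two defining variants from a [geno_matrix()], orients their
#' dosages so they count the C allele at each site, and calls diplotypes via
#' [call_from_dosages()].
#'
#' @param geno a [geno_matrix()] containing both variants.
#' @param rs429358,rs7412 variant IDs of the two sites in `geno`.
#' @param band hard-call band (see [call_from_dosages()]).
#' @return Tibble of APOE calls, one row per individual.
#' @export
call_apoe <- function(geno, rs429358 = "rs429358", rs7412 = "rs7412", band = 0.1) {
  g <- subset_variants(geno, c(rs429358, rs7412))
  v <- g$variants
  orient <- function(i) {
    counted <- v$counted_allele[i]; alt <- v$alt_allele[i]
    if (counted == "C") g$dosages[, i]
    else if (alt == "C") 2 - g$dosages[, i]
    else abort(paste0("call_apoe: variant ", v$variant_id[i],
                      " has no C allele; check allele coding"))
  }
  call_from_dosages(orient(1), orient(2), band = band,
                    individual_id = individual_ids(g))
}

#' Write APOE calls as a tab-delimited table
#'
#' @param calls tibble from [call_apoe()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_apoe_calls <- function(calls, path) {
  readr::write_tsv(calls, path, na = "NA", progress = FALSE)
  invisible(path)
}
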