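# The packaged default panel: 17 targeted steroids (quantified against
# analyte-specific isotopically labelled internal standards, with validated
# LLOQ/ULOQ) plus 34 untargeted steroids quantified by surrogate
# calibration against A4 (C19 skeletons) or P4 (C21 skeletons).
#
# m/z values are [M+H]+ / [M-H]- monoisotopic ions computed from the
# molecular formula. Retention times are plausible elution positions on a
# 17-min reversed-phase gradient, not instrument measurements. Only the
# 11KA4 correction factor (0.329 vs A4) is an experimentally established
# value; every other factor is a documented placeholder of 1.0 flagged
# `cf_verified = FALSE`, to be replaced by user-measured response factors.

# abbreviation, full_name, class, mode, polarity, formula, rt, is_ref|surrogate
.TARGETED <- list(
  #            abbrev             full name                   class              formula      rt    IS              lloq   uloq
  list("P4",               "progesterone",             "progestogen",       "C21H30O2", 10.9, "d9-P4",            0.476, 1590),
  list("P5",               "pregnenolone",             "precursor",         "C21H32O2", 11.3, "d4-P5",            0.771, 790),
  list("17OHP4",           "17a-hydroxyprogesterone",  "progestogen",       "C21H30O3",  9.2, "d8-17OHP4",        0.092, 189),
  list("A4",               "androstenedione",          "androgen",          "C19H26O2",  8.0, "d7-A4",            0.107, 218),
  list("T",                "testosterone",             "androgen",          "C19H28O2",  8.4, "d3-T",             0.105, 867),
  list("DHT",              "5a-dihydrotestosterone",   "androgen",          "C19H30O2",  9.6, "d3-DHT",           0.105, 215),
  list("An",               "androsterone",             "androgen",          "C19H30O2", 10.2, "d4-An",            0.420, 861),
  list("Etio",             "etiocholanolone",          "androgen",          "C19H30O2", 10.6, "d4-An",            0.210, 215),
  list("DHEA",             "dehydroepiandrosterone",   "androgen",          "C19H28O2",  8.8, "d6-DHEA",          0.846, 867),
  list("DHEAS",            "DHEA sulfate",             "androgen",          "C19H28O5S", 3.5, "d6-DHEAS",         6.252, 12805),
  list("cortisol",         "cortisol",                 "glucocorticoid",    "C21H30O5",  5.2, "d4-cortisol",      0.378, 8967),
  list("cortisone",        "cortisone",                "glucocorticoid",    "C21H28O5",  4.9, "d4-cortisol",      0.177, 1387),
  list("corticosterone",   "corticosterone",           "mineralocorticoid", "C21H30O4",  6.5, "d8-corticosterone", 0.705, 1443),
  list("11DOC",            "11-deoxycorticosterone",   "mineralocorticoid", "C21H30O3",  7.8, "d8-corticosterone", 0.092, 189),
  list("11deoxycortisol",  "11-deoxycortisol",         "glucocorticoid",    "C21H30O4",  6.9, "d5-11-deoxycortisol", 0.088, 180),
  list("21deoxycortisol",  "21-deoxycortisol",         "glucocorticoid",    "C21H30O4",  6.2, "d5-11-deoxycortisol", 0.088, 180),
  list("aldosterone",      "aldosterone",              "mineralocorticoid", "C21H28O5",  4.5, "d7-aldosterone",   0.085, 173)
)

.UNTARGETED <- list(
  # C11-oxy androgens (surrogate A4)
  list("11OHA4",       "11b-hydroxyandrostenedione",        "C11-oxy androgen", "C19H26O3",  6.0, "A4"),
  list("11KA4",        "11-ketoandrostenedione",            "C11-oxy androgen", "C19H24O3",  6.2, "A4"),
  list("11KT",         "11-ketotestosterone",               "C11-oxy androgen", "C19H26O3",  6.4, "A4"),
  list("11OHT",        "11b-hydroxytestosterone",           "C11-oxy androgen", "C19H28O3",  6.6, "A4"),
  list("11K5aDIONE",   "5a-androstanetrione",               "C11-oxy androgen", "C19H26O3",  7.0, "A4"),
  list("11OH5aDIONE",  "11b-hydroxy-5a-androstanedione",    "C11-oxy androgen", "C19H28O3",  7.1, "A4"),
  list("11KDHT",       "11-ketodihydrotestosterone",        "C11-oxy androgen", "C19H28O3",  7.5, "A4"),
  list("11KAn",        "11-ketoandrosterone",               "C11-oxy androgen", "C19H28O3",  8.1, "A4"),
  list("11OHAn",       "11b-hydroxyandrosterone",           "C11-oxy androgen", "C19H30O3",  7.7, "A4"),
  # classical androgens / precursors (surrogate A4)
  list("5aDIONE",      "5a-androstanedione",                "androgen",  "C19H28O2",  9.9, "A4"),
  list("epiT",         "epitestosterone",                   "androgen",  "C19H28O2",  9.3, "A4"),
  list("A5",           "androstenediol",                    "androgen",  "C19H30O2",  9.0, "A4"),
  list("16OHDHEA",     "16a-hydroxy-DHEA",                  "androgen",  "C19H28O3",  5.8, "A4"),
  list("3a5aAdiol",    "5a-androstane-3a,17b-diol",         "androgen",  "C19H32O2", 10.4, "A4"),
  # progesterone metabolites (surrogate P4)
  list("20aOHP4",      "20a-hydroxyprogesterone",           "progestogen", "C21H32O2",  9.8, "P4"),
  list("5aDHP4",       "5a-dihydroprogesterone",            "progestogen", "C21H32O2", 11.9, "P4"),
  list("5bDHP4",       "5b-dihydroprogesterone",            "progestogen", "C21H32O2", 10.6, "P4"),
  list("11aOHP4",      "11a-hydroxyprogesterone",           "progestogen", "C21H30O3",  7.0, "P4"),
  list("11bOHP4",      "11b-hydroxyprogesterone",           "progestogen", "C21H30O3",  6.5, "P4"),
  list("16aOHP4",      "16a-hydroxyprogesterone",           "progestogen", "C21H30O3",  7.4, "P4"),
  list("6aOHP4",       "6a-hydroxyprogesterone",            "progestogen", "C21H30O3",  6.0, "P4"),
  list("1720diOHP4",   "17a,20a-dihydroxyprogesterone",     "progestogen", "C21H32O3",  7.5, "P4"),
  list("11KP4",        "11-ketoprogesterone",               "progestogen", "C21H28O3",  8.2, "P4"),
  list("AlloP4",       "allopregnanolone",                  "progestogen", "C21H34O2", 11.5, "P4"),
  list("Pdiol",        "pregnanediol",                      "progestogen", "C21H36O2", 11.8, "P4"),
  list("Ptriol",       "pregnanetriol",                     "progestogen", "C21H36O3",  8.9, "P4"),
  list("11KPtriol",    "11-ketopregnanetriol",              "progestogen", "C21H34O4",  5.9, "P4"),
  list("17OHP5",       "17a-hydroxypregnenolone",           "precursor",   "C21H32O3",  9.4, "P4"),
  # corticosteroid metabolites (surrogate P4)
  list("THE",          "tetrahydrocortisone",               "glucocorticoid",    "C21H32O5", 5.0, "P4"),
  list("THF",          "tetrahydrocortisol",                "glucocorticoid",    "C21H34O5", 5.4, "P4"),
  list("5aTHF",        "allotetrahydrocortisol",            "glucocorticoid",    "C21H34O5", 5.9, "P4"),
  list("18OHF",        "18-hydroxycortisol",                "glucocorticoid",    "C21H30O6", 4.1, "P4"),
  list("THB",          "tetrahydrocorticosterone",          "mineralocorticoid", "C21H34O4", 6.6, "P4"),
  list("18OHB",        "18-hydroxycorticosterone",          "mineralocorticoid", "C21H30O5", 4.6, "P4")
)

# 13 labelled standards covering the elution-time range; spike amount is
# 38 uL x 3.8 nmol/L = 0.1444 pmol per 500-uL sample.
.INTERNAL_STANDARDS <- list(
  #    id                      labels            formula        rt    polarity of analyte
  list("d9-P4",                "P4",             "C21H21D9O2", 10.9),
  list("d4-P5",                "P5",             "C21H28D4O2", 11.3),
  list("d8-17OHP4",            "17OHP4",         "C21H22D8O3",  9.2),
  list("d7-A4",                "A4",             "C19H19D7O2",  8.0),
  list("d3-T",                 "T",              "C19H25D3O2",  8.4),
  list("d3-DHT",               "DHT",            "C19H27D3O2",  9.6),
  list("d4-An",                "An",             "C19H26D4O2", 10.2),
  list("d6-DHEA",              "DHEA",           "C19H22D6O2",  8.8),
  list("d6-DHEAS",             "DHEAS",          "C19H22D6O5S", 3.5),
  list("d4-cortisol",          "cortisol",       "C21H26D4O5",  5.2),
  list("d8-corticosterone",    "corticosterone", "C21H22D8O4",  6.5),
  list("d5-11-deoxycortisol",  "11deoxycortisol", "C21H25D5O4", 6.9),
  list("d7-aldosterone",       "aldosterone",    "C21H21D7O5",  4.5)
)

# Product/substrate pairs for apparent enzyme activities named in the
# steroidogenic pathway map.
.ENZYME_RATIOS <- list(
  list("CYP17A1",        "CYP17A1", "17OHP4",   "P4"),
  list("HSD3B2",         "HSD3B2",  "P4",       "P5"),
  list("HSD11B2_cortisol", "HSD11B2", "cortisone", "cortisol"),
  list("HSD11B2_11KA4",  "HSD11B2", "11KA4",    "11OHA4"),
  list("HSD11B2_11KT",   "HSD11B2", "11KT",     "11OHT"),
  list("SRD5A_A4",       "SRD5A",   "5aDIONE",  "A4"),
  list("SRD5A_T",        "SRD5A",   "DHT",      "T"),
  list("SRD5A_P4",       "SRD5A",   "5aDHP4",   "P4"),
  list("HSD17B_T",       "HSD17B",  "T",        "A4"),
  list("HSD17B_11KT",    "HSD17B",  "11KT",     "11KA4"),
  list("CYP21A2",        "CYP21A2", "11DOC",    "P4")
)

#' The default 51-steroid panel
#'
#' Builds the packaged panel: 17 targeted steroids with validated
#' LLOQ/ULOQ ranges, 34 untargeted steroids assigned to the surrogates A4
#' (C19 androgens) or P4 (C21 progestogens and corticoid metabolites), 13
#' isotopically labelled internal standards, and the default enzyme-ratio
#' definitions. The only experimentally verified correction factor shipped
#' is 11KA4 vs A4 (0.329); all other factors default to 1.0 and are flagged
#' `cf_verified = FALSE` so that downstream results carry an
#' `unverified_factor` flag until user-measured factors are configured.
#'
#' @return A `steroid_panel` with 51 steroids.
#' @examples
#' p <- default_panel()
#' table(p$steroids$quant_mode)
#' @export
default_panel <- function() {
  tg <- dplyr::bind_rows(lapply(.TARGETED, function(r) tibble::tibble(
    abbreviation = r[[1]], full_name = r[[2]], steroid_class = r[[3]],
    quant_mode = "targeted",
    polarity = if (r[[1]] == "DHEAS") "negative" else "positive",
    formula = r[[4]], expected_rt = r[[5]], is_ref = r[[6]],
    lloq = r[[7]], uloq = r[[8]]
  )))
  ut <- dplyr::bind_rows(lapply(.UNTARGETED, function(r) tibble::tibble(
    abbreviation = r[[1]], full_name = r[[2]], steroid_class = r[[3]],
    quant_mode = "untargeted", polarity = "positive",
    formula = r[[4]], expected_rt = r[[5]], surrogate_ref = r[[6]],
    correction_factor = if (r[[1]] == "11KA4") 0.329 else 1.0,
    cf_verified = r[[1]] == "11KA4"
  )))
  steroids <- dplyr::bind_rows(tg, ut)
  steroids$mz <- ion_mz_vec(steroids$formula, steroids$polarity)
  istd <- dplyr::bind_rows(lapply(.INTERNAL_STANDARDS, function(r) tibble::tibble(
    id = r[[1]], labels_analyte = r[[2]], formula = r[[3]],
    expected_rt = r[[4]], spike_amount_pmol = 0.1444
  )))
  istd$mz <- ion_mz_vec(istd$formula,
                        ifelse(istd$id == "d6-DHEAS", "negative", "positive"))
  er <- dplyr::bind_rows(lapply(.ENZYME_RATIOS, function(r) tibble::tibble(
    ratio_id = r[[1]], enzyme = r[[2]],
    products = list(r[[3]]), substrates = list(r[[4]])
  )))
  steroid_panel(steroids, istd, er,
                calibration = list(range = c(0.1, 2000), n_levels = 12L))
}

ion_mz_vec <- function(formula, polarity) {
  mapply(function(f, p) ion_mz(f, p), formula, polarity, USE.NAMES = FALSE)
}
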