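# Shared fixtures: a minimal hand-built panel used by unit tests where the
# full 51-steroid default panel would obscure the behaviour under test.

tiny_panel <- function() {
  steroids <- tibble::tibble(
    abbreviation = c("A4", "P4", "cortisol", "11KA4", "20aOHP4"),
    full_name = c("androstenedione", "progesterone", "cortisol",
                  "11-ketoandrostenedione", "20a-hydroxyprogesterone"),
    steroid_class = c("androgen", "progestogen", "glucocorticoid",
                      "C11-oxy androgen", "progestogen"),
    quant_mode = c("targeted", "targeted", "targeted", "untargeted", "untargeted"),
    polarity = "positive",
    formula = c("C19H26O2", "C21H30O2", "C21H30O5", "C19H24O3", "C21H32O2"),
    expected_rt = c(8.0, 10.9, 5.2, 6.2, 9.8),
    is_ref = c("d7-A4", "d9-P4", "d4-cortisol", NA, NA),
    surrogate_ref = c(NA, NA, NA, "A4", "P4"),
    correction_factor = c(NA, NA, NA, 0.329, 1.0),
    cf_verified = c(NA, NA, NA, TRUE, FALSE),
    lloq = c(0.107, 0.476, 0.378, NA, NA),
    uloq = c(218, 1590, 8967, NA, NA)
  )
  steroids$mz <- steroquant::ion_mz(steroids$formula, "positive")
  istd <- tibble::tibble(
    id = c("d7-A4", "d9-P4", "d4-cortisol"),
    labels_analyte = c("A4", "P4", "cortisol"),
    formula = c("C19H19D7O2", "C21H21D9O2", "C21H26D4O5"),
    expected_rt = c(8.0, 10.9, 5.2),
    spike_amount_pmol = 0.1444
  )
  istd$mz <- steroquant::ion_mz(istd$formula, "positive")
  er <- tibble::tibble(
    ratio_id = "CYP17A1", enzyme = "CYP17A1",
    products = list("P4"), substrates = list("cortisol")
  )
  # nonsense biology for the ratio, but resolvable references
  steroid_panel(steroids, istd, er)
}

# exhaustive permutation enumeration (test oracle, kept independent of the
# package internals): builds the n! x n matrix row by row from index tuples
gtools_permutations <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid <- grid[apply(grid, 1, function(r) length(unique(r)) == n), , drop = FALSE]
  unname(grid)
}

# deterministic gaussian peak trace on a fixed rt grid
gaussian_trace <- function(center = 5, sigma = 0.03, height = 1e4,
                           from = 4, to = 6, by = 0.005) {
  rt <- seq(from, to, by = by)
  tibble::tibble(rt = rt,
                 intensity = height * exp(-(rt - center)^2 / (2 * sigma^2)))
}

# writes a minimal centroided mzML file (64-bit float, no compression) so
# the reader can be exercised without instrument data
write_minimal_mzml <- function(path, scans) {
  b64 <- function(x) jsonlite::base64_enc(writeBin(x, raw(), size = 8,
                                                   endian = "little"))
  spec <- function(idx, rt_sec, mz, int) {
    n <- length(mz)
    sprintf(paste0(
      "<spectrum index=\"%d\" id=\"scan=%d\" defaultArrayLength=\"%d\">",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000511\" name=\"ms level\" value=\"1\"/>",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000127\" name=\"centroid spectrum\" value=\"\"/>",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000130\" name=\"positive scan\" value=\"\"/>",
      "<scanList count=\"1\"><scan><cvParam cvRef=\"MS\" accession=\"MS:1000016\" ",
      "name=\"scan start time\" value=\"%f\" unitName=\"second\" unitAccession=\"UO:0000010\"/>",
      "</scan></scanList><binaryDataArrayList count=\"2\">",
      "<binaryDataArray encodedLength=\"%d\"><cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\" value=\"\"/>",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\" value=\"\"/>",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000514\" name=\"m/z array\" value=\"\"/>",
      "<binary>%s</binary></binaryDataArray>",
      "<binaryDataArray encodedLength=\"%d\"><cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\" value=\"\"/>",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\" value=\"\"/>",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000515\" name=\"intensity array\" value=\"\"/>",
      "<binary>%s</binary></binaryDataArray></binaryDataArrayList></spectrum>"),
      idx, idx + 1, n, rt_sec, nchar(b64(mz)), b64(mz), nchar(b64(int)), b64(int))
  }
  body <- paste0(vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    spec(i - 1, s$rt_min * 60, s$mz, s$intensity)
  }, character(1)), collapse = "")
  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"utf-8\"?>",
    "<mzML xmlns=\"http://psi.hupo.org/ms/mzml\" version=\"1.1.0\">",
    "<cvList count=\"1\"><cv id=\"MS\" fullName=\"PSI-MS\" URI=\"x\"/></cvList>",
    "<run id=\"r1\"><spectrumList count=\"", length(scans),
    "\" defaultDataProcessingRef=\"dp\">", body, "</spectrumList></run></mzML>")
  writeLines(doc, path)
  path
}
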