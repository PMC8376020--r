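# Small in-code fixtures shared across test files.

# A hand-built 3-site x 2-season table on one network ("Provo"-like), with
# the max-area site flagged as outlet.
tiny_table <- function() {
  as_site_table(tibble::tibble(
    site_id = rep(c("A", "B", "C"), 2),
    network = "Provo",
    category = "MixedDammed",
    area_km2 = rep(c(10, 40, 100), 2),
    season = rep(c("Spring", "Summer"), each = 3),
    forest = 0.6, developed = 0.1, impervious = 0.03, herbaceous = 0.1,
    DOC = c(1, 2, 3, 2, 4, 6),
    TDN = c(0.5, 1.0, 1.5, 0.4, 0.8, 1.2),
    DIN = NA_real_, PO4 = NA_real_, Cl = 50, SO4 = 40,
    is_outlet = rep(c(FALSE, FALSE, TRUE), 2)))
}

# Write a CSV fixture and return its path.
write_fixture_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "sites.csv")
  readr::write_csv(df, path, na = "")
  path
}

# A deterministic conservative-mixing network built by hand: 4 leaves whose
# areas partition the outlet, internal nodes exact flux-weighted means.
conservative_fixture <- function() {
  a <- c(L1 = 10, L2 = 30, L3 = 25, L4 = 35)
  conc <- c(L1 = 2.0, L2 = 0.5, L3 = 3.0, L4 = 1.0)
  n1 <- sum(conc[c("L1", "L2")] * a[c("L1", "L2")]) / sum(a[c("L1", "L2")])
  n2 <- sum(conc[c("L3", "L4")] * a[c("L3", "L4")]) / sum(a[c("L3", "L4")])
  out <- (n1 * 40 + n2 * 60) / 100
  as_site_table(tibble::tibble(
    site_id = c("L1", "L2", "L3", "L4", "N1", "N2", "OUT"),
    network = "SpanishFork",
    category = "AgriculturalUnregulated",
    area_km2 = c(10, 30, 25, 35, 40, 60, 100),
    season = "Spring",
    forest = 0.5, developed = 0.1, impervious = 0.02, herbaceous = 0.2,
    DOC = c(2.0, 0.5, 3.0, 1.0, n1, n2, out),
    TDN = NA_real_, DIN = NA_real_, PO4 = NA_real_,
    Cl = NA_real_, SO4 = NA_real_,
    is_outlet = c(rep(FALSE, 6), TRUE)))
}
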