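test_that("composition parsing is order-insensitive, canonicalizing and strict", {
  p <- parse_glycan("HexNAc(6)Hex(7)Fuc(1)NeuAc(4)")
  expect_equal(p$hexnac, 6L)
  expect_equal(p$hex, 7L)
  expect_equal(p$fuc, 1L)
  expect_equal(p$neuac, 4L)

  p2 <- parse_glycan("HexNAc(4)Hex(5)NeuAc(2)")
  expect_equal(c(p2$hexnac, p2$hex, p2$fuc, p2$neuac), c(4L, 5L, 0L, 2L))

  # order-insensitive, output canonical
  expect_equal(parse_glycan("NeuAc(4)Fuc(1)Hex(7)HexNAc(6)")$composition,
               "HexNAc(6)Hex(7)Fuc(1)NeuAc(4)")

  # round-trip: parse o format = identity; format o parse idempotent
  comps <- c("HexNAc(2)Hex(8)", "HexNAc(4)Hex(5)NeuAc(2)", "Fuc(2)",
             "HexNAc(6)Hex(7)Fuc(3)NeuAc(3)")
  reparsed <- parse_glycan(parse_glycan(comps)$composition)
  expect_equal(reparsed$composition, comps)

  expect_error(parse_glycan(""), class = "glyco_parse_error")
  expect_error(parse_glycan("HexNAc(2)Pent(1)"), class = "glyco_parse_error")
  expect_error(parse_glycan("HexNAc(-1)"), class = "glyco_parse_error")
  expect_error(parse_glycan("HexNAc(1.5)"), class = "glyco_parse_error")
  expect_error(parse_glycan("HexNAc(2)HexNAc(1)"), class = "glyco_parse_error")
  expect_error(parse_glycan("HexNAc(2)junk"), class = "glyco_parse_error")
})

test_that("glycan mass is additive and reproduces the hand-derived anchors", {
  # 2 HexNAc + 3 Hex summed by hand: 2*203.07937 + 3*162.05282 = 892.3172
  expect_equal(glycan_mass("HexNAc(2)Hex(3)"), 892.3172, tolerance = 5e-4 / 892)
  # the 2Fuc vs 1NeuAc isobaric gap
  expect_equal(round(glycan_mass("Fuc(2)") - glycan_mass("NeuAc(1)"), 2), 1.02)
  # empty composition has mass exactly 0
  zero <- tibble::tibble(hexnac = 0L, hex = 0L, fuc = 0L, neuac = 0L)
  expect_identical(glycan_mass(zero), 0)

  # additivity / linearity over random counts
  set.seed(42)
  for (i in 1:20) {
    a <- tibble::tibble(hexnac = sample(0:6, 1), hex = sample(0:9, 1),
                        fuc = sample(0:4, 1), neuac = sample(0:4, 1))
    b <- tibble::tibble(hexnac = sample(0:6, 1), hex = sample(0:9, 1),
                        fuc = sample(0:4, 1), neuac = sample(0:4, 1))
    ab <- a + b
    expect_equal(glycan_mass(ab), glycan_mass(a) + glycan_mass(b))
  }
})

test_that("oxonium m/z matches the diagnostic-ion values", {
  expect_equal(round(oxonium_mz("Hex(1)HexNAc(1)Fuc(1)"), 2), 512.20)
  expect_equal(round(oxonium_mz("NeuAc(1)", water_losses = 1), 3), 274.092)
  expect_equal(oxonium_mz("HexNAc(1)"), 204.0866, tolerance = 1e-3 / 204)
  expect_error(oxonium_mz(tibble::tibble(hexnac = 0L, hex = 0L, fuc = 0L,
                                         neuac = 0L)),
               class = "glyco_domain_error")
})

test_that("classification reproduces the labelled example structures", {
  cls <- classify_glycans(c(
    "HexNAc(2)Hex(8)",                 # high-mannose marker composition
    "HexNAc(4)Hex(5)NeuAc(2)",         # biantennary, two sialic acids
    "HexNAc(5)Hex(5)NeuAc(1)",         # bisected biantennary
    "HexNAc(6)Hex(7)Fuc(1)NeuAc(4)"    # tetra-antennary
  ))
  expect_equal(cls$family, c("high-mannose", "complex", "complex", "complex"))
  expect_equal(cls$antennae, c(0L, 2L, 2L, 4L))
  expect_equal(cls$bisecting, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(cls$sialylation, c(0L, 2L, 1L, 4L))
})

test_that("classification is total, deterministic and obeys its invariants", {
  grid <- tidyr::expand_grid(hexnac = 0:7, hex = 0:10, fuc = 0:4, neuac = 0:4)
  grid <- grid[rowSums(grid) > 0, ]
  comps <- format_glycan(grid$hexnac, grid$hex, grid$fuc, grid$neuac)
  cls <- classify_glycans(comps)
  expect_true(all(cls$family %in% c("high-mannose", "complex", "hybrid",
                                    "paucimannose/other")))
  hm <- cls$family == "high-mannose"
  expect_true(all(grid$hexnac[hm] == 2 & grid$fuc[hm] == 0 & grid$neuac[hm] == 0))
  # antennae 2-4 only for complex glycans
  expect_true(all(cls$family[cls$antennae >= 2] == "complex"))
  # no bisecting flag when galactoses account for every antenna
  balanced <- cls$family == "complex" & (grid$hex - 3 >= grid$hexnac - 2)
  expect_true(all(!cls$bisecting[balanced]))
  # deterministic
  expect_identical(cls, classify_glycans(comps))
})

test_that("isobaric alternatives find the Fuc/NeuAc swap via an isotope error", {
  alt <- isobaric_alternatives("HexNAc(6)Hex(7)Fuc(3)NeuAc(3)",
                               reference_mass = 4000, tolerance_ppm = 20,
                               isotope_errors = -1:1)
  expect_true("HexNAc(6)Hex(7)Fuc(1)NeuAc(4)" %in% alt$composition)
  # the query is always its own group member with delta 0, isotope 0
  self <- alt[alt$composition == "HexNAc(6)Hex(7)Fuc(3)NeuAc(3)", ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$delta_da, 0)
  expect_equal(self$isotope_k, 0L)

  # with no isotope error allowed, the 1.02 Da swap exceeds a 10 ppm window
  alt0 <- isobaric_alternatives("HexNAc(6)Hex(7)Fuc(3)NeuAc(3)",
                                reference_mass = 4000, tolerance_ppm = 10,
                                isotope_errors = 0)
  expect_false("HexNAc(6)Hex(7)Fuc(1)NeuAc(4)" %in% alt0$composition)
})

test_that("isobaric alternatives are symmetric", {
  queries <- c("HexNAc(6)Hex(7)Fuc(3)NeuAc(3)", "HexNAc(4)Hex(5)NeuAc(2)",
               "HexNAc(5)Hex(6)Fuc(1)NeuAc(2)")
  for (q in queries) {
    alt <- isobaric_alternatives(q, reference_mass = 4000)
    for (i in seq_len(nrow(alt))) {
      back <- isobaric_alternatives(alt$composition[i], reference_mass = 4000)
      j <- which(back$composition == parse_glycan(q)$composition)
      expect_length(j, 1L)
      expect_equal(back$delta_da[j], -alt$delta_da[i], tolerance = 1e-9)
      if (alt$composition[i] != parse_glycan(q)$composition) {
        expect_equal(back$isotope_k[j], -alt$isotope_k[i])
      }
    }
  }
})

test_that("diagnostic ion check matches peaks within ppm tolerance only", {
  ev <- diagnostic_ion_check(data.frame(mz = c(512.197, 274.092),
                                        intensity = c(100, 50)))
  expect_true(ev$core_fucose)
  expect_true(ev$sialic_acid)
  expect_true(is.na(ev$antennary_fucose))

  # empty peak list: everything absent
  ev0 <- diagnostic_ion_check(data.frame(mz = numeric(0), intensity = numeric(0)))
  expect_false(ev0$core_fucose)
  expect_false(ev0$sialic_acid)

  # a 200 ppm miss is not a match at 20 ppm
  ev_miss <- diagnostic_ion_check(data.frame(mz = 512.30, intensity = 1),
                                  tolerance_ppm = 20)
  expect_false(ev_miss$core_fucose)

  # antennary fucose needs the peptide mass; target is pep+2HexNAc+Fuc+proton
  pep_mass <- 1000
  target <- pep_mass + 2 * 203.07937 + 146.05791 + 1.007276
  ev_ant <- diagnostic_ion_check(data.frame(mz = target, intensity = 1),
                                 peptide_mass = pep_mass)
  expect_true(ev_ant$antennary_fucose)
  expect_true(all(abs(ev_ant$matches$ppm_error) <= 20))
})
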