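test_that("contact type index is a symmetric bijection over the 210 pairs", {
  nm <- contact_type_names()
  expect_length(nm, 210L)
  expect_equal(anyDuplicated(nm), 0L)
  # every unordered pair maps to a unique slot, symmetrically
  idx <- outer(seq_len(20L), seq_len(20L),
               Vectorize(function(a, b) contact_type_index(a, b)))
  expect_true(all(idx == t(idx)))
  expect_equal(sort(unique(as.vector(idx))), 1:210)
  # canonical order: row-major upper triangle, alphabetical 3-letter codes
  expect_equal(nm[contact_type_index("ALA", "ALA")], "ALA-ALA")
  expect_equal(nm[contact_type_index("VAL", "ALA")], "ALA-VAL")
  expect_equal(nm[contact_type_index("GLY", "HIS")], "GLY-HIS")
  expect_error(contact_type_index("FOO", "ALA"), "nonstandard")
})

test_that("forced two-residue contact is recovered; zero cutoff empties the map", {
  # two single-atom residues 3 A apart plus 3 distant padding atoms
  atoms <- data.frame(
    res = c(1L, 2L, 3L, 4L, 5L),
    x = c(0, 3, 50, 60, 70),
    y = c(0, 0, 50, -40, 80),
    z = c(0, 0, 50, 60, -70)
  )
  ch <- protein_chain("A", c("ALA", "GLY", "LEU", "SER", "THR"), atoms)
  map <- build_contact_map(ch, cutoff = 4.5, min_separation = 1L)
  expect_equal(as.data.frame(map), data.frame(i = 1L, j = 2L))
  expect_equal(nrow(build_contact_map(ch, cutoff = 0)), 0L)
  expect_error(build_contact_map(ch, cutoff = -1), ">= 0")
})

test_that("chains with fewer than 5 atoms are rejected as degenerate", {
  atoms <- data.frame(res = c(1L, 2L), x = c(0, 3), y = 0, z = 0)
  ch <- protein_chain("A", c("ALA", "GLY"), atoms)
  expect_error(build_contact_map(ch), "degenerate")
})

test_that("contact map equals the scipy Delaunay brute-force enumeration", {
  for (seed in c(7L, 21L)) {
    ch <- make_toy_chain(30L, seed = seed)
    coords <- fitscape:::chain_coords(ch)
    oracle <- scipy_residue_contacts(coords, ch$atoms$res, 4.5, 2L)
    mine <- as.data.frame(build_contact_map(ch))[c("i", "j")]
    expect_equal(mine, oracle)
  }
})

test_that("contact map is rigid-motion invariant and within the cutoff graph", {
  ch <- make_toy_chain(25L, seed = 3L)
  map <- build_contact_map(ch)
  # random rotation + translation
  withr::with_seed(99L, {
    qr_ <- qr(matrix(rnorm(9L), 3L))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1L] <- -R[, 1L]
    shift <- rnorm(3L, sd = 20)
  })
  xyz <- as.matrix(ch$atoms[c("x", "y", "z")]) %*% R
  ch2 <- ch
  ch2$atoms[c("x", "y", "z")] <- sweep(xyz, 2L, -shift)
  expect_equal(as.data.frame(build_contact_map(ch2)), as.data.frame(map))
  # Delaunay-filtered map is a subset of the plain distance-cutoff graph
  co <- fitscape:::chain_coords(ch)
  cand <- fitscape:::candidate_pairs(co, ch$atoms$res, 4.5, 2L)
  plain <- unique(paste(cand$ri, cand$rj))
  expect_true(all(paste(map$i, map$j) %in% plain))
})

test_that("contact vectors count types correctly and conserve the map size", {
  ch <- make_toy_chain(30L, seed = 11L)
  map <- build_contact_map(ch)
  v <- contact_vector(ch, map)
  expect_s3_class(v, "contact_vector")
  expect_equal(sum(v), nrow(map))
  expect_true(all(as.numeric(v) == floor(as.numeric(v))))
  expect_equal(as.numeric(v), brute_recount(map, ch$res_type))
  # empty map -> zero vector
  empty <- fitscape:::contact_map(data.frame(i = integer(), j = integer()),
                                  n = length(ch$res_type))
  expect_equal(sum(contact_vector(ch, empty)), 0)
  # decoy sequence on the native map: known single-contact placement
  atoms <- data.frame(res = 1:5, x = c(0, 4, 8, 40, 44), y = 0, z = 0)
  ch3 <- protein_chain("B", rep("ALA", 5L), atoms)
  m3 <- fitscape:::contact_map(data.frame(i = 1L, j = 3L), n = 5L)
  v3 <- contact_vector(ch3, m3, sequence = c("ALA", "GLY", "ALA", "GLY", "GLY"))
  expect_equal(sum(v3), 1)
  expect_equal(as.numeric(v3)[contact_type_index("ALA", "ALA")], 1)
  expect_error(contact_vector(ch3, m3, sequence = c("ALA", "GLY")), "length")
  expect_error(contact_vector(ch3, m3, sequence = c("ALA", "GLY", "XXX", "GLY", "GLY")),
               "nonstandard")
})

test_that("the vector depends only on residue types at contacting positions", {
  ch <- make_toy_chain(30L, seed = 13L)
  map <- build_contact_map(ch)
  v <- contact_vector(ch, map)
  touching <- unique(c(map$i, map$j))
  free <- setdiff(seq_along(ch$res_type), touching)
  expect_gte(length(free), 2L) # this chain has never-contacting residues
  s2 <- ch$res_type
  withr::with_seed(1L, s2[free] <- sample(s2[free]))
  expect_equal(as.numeric(contact_vector(ch, map, sequence = s2)), as.numeric(v))
})

test_that("length model fits exact lines and recovers simulated coefficients", {
  # points exactly on Nc = 2n
  exact <- fit_length_model(data.frame(length = c(50, 100, 150), total = c(100, 200, 300)))
  expect_equal(exact$a, 0, tolerance = 1e-10)
  expect_equal(exact$b, 2, tolerance = 1e-10)
  # two-point line
  two <- fit_length_model(data.frame(length = c(50, 100), total = c(120, 220)))
  expect_equal(two$b, 2, tolerance = 1e-10)
  expect_equal(two$a, 20, tolerance = 1e-10)
  # parameter recovery on simulation
  withr::with_seed(17L, {
    n <- sample(46:500, 120L, replace = TRUE)
    tot <- 15 + 2.8 * n + rnorm(120L, sd = 8)
  })
  fit <- fit_length_model(data.frame(length = n, total = tot))
  expect_lt(abs(fit$a - 15), 3 * fit$se[1L])
  expect_lt(abs(fit$b - 2.8), 3 * fit$se[2L])
  expect_error(fit_length_model(data.frame(length = c(70, 70, 70),
                                           total = c(100, 110, 120))),
               "singular")
})

test_that("length normalization scales by predicted totals and inverts cleanly", {
  model <- structure(list(a = 10, b = 3, se = c(NA, NA), n = 3L),
                     class = "length_model")
  v <- fitscape:::new_contact_vector(c(predict_contacts(model, 100), rep(0, 209L)),
                                     length = 100L)
  nv <- normalize_length(v, model)
  expect_equal(sum(nv), 1) # on-the-line protein: normalized total = 1
  expect_true(attr(nv, "normalized"))
  expect_error(normalize_length(nv, model), "already normalized")
  back <- denormalize_length(nv)
  expect_equal(as.numeric(back), as.numeric(v))
  # zero vector stays zero
  z <- fitscape:::new_contact_vector(numeric(210L), length = 80L)
  expect_equal(sum(normalize_length(z, model)), 0)
  # negative predicted total is an error
  bad <- structure(list(a = -500, b = 1, se = c(NA, NA), n = 3L),
                   class = "length_model")
  expect_error(normalize_length(v, bad), "non-positive")
  # reference-length variant rescales to a common length
  rv <- normalize_length(v, model, method = "reference-length", ref_length = 100L)
  expect_equal(as.numeric(rv), as.numeric(v)) # same length as reference
})

test_that("curation applies length, residue-quality and inter-chain filters", {
  mk <- function(n, codes = NULL, resno = NULL) {
    ch <- make_toy_chain(n, seed = n)
    if (!is.null(codes)) ch$res_type <- codes
    if (!is.null(resno)) ch$resno <- resno
    ch
  }
  expect_equal(curate_chain(mk(45L))$reason, "length")
  expect_equal(curate_chain(mk(501L))$reason, "length")
  expect_true(curate_chain(mk(100L))$accept)
  amb <- mk(60L)
  amb$res_type[10L] <- "ASX"
  expect_equal(curate_chain(amb)$reason, "ambiguous-residues")
  gap <- mk(60L, resno = c(1:30, 41:70))
  expect_equal(curate_chain(gap)$reason, "missing-residues")
  expect_error(curate_chain(list(not = "a chain")), "protein_chain")
})

test_that("a tight synthetic dimer is rejected for extensive inter-chain contacts", {
  ch <- make_toy_chain(50L, seed = 31L)
  partner <- ch
  partner$chain_id <- "B"
  # overlay the partner right next to the chain so many residues touch it
  partner$atoms$x <- partner$atoms$x + 3.5
  frac <- fitscape:::interchain_fraction(ch, list(partner))
  expect_gt(frac, 0.30)
  expect_equal(curate_chain(ch, partners = list(partner))$reason, "inter-chain")
  # far-away partner: no inter-chain contacts, chain accepted
  far <- partner
  far$atoms$x <- far$atoms$x + 500
  expect_true(curate_chain(ch, partners = list(far))$accept)
})

test_that("PDB round trip preserves sequence, length and contacts", {
  ch <- make_toy_chain(40L, seed = 4L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(ch, path)
  back <- read_pdb_chain(path, chain_id = "A")
  expect_equal(back$res_type, ch$res_type)
  expect_equal(length(back), length(ch))
  expect_equal(as.data.frame(build_contact_map(back)),
               as.data.frame(build_contact_map(ch)),
               tolerance = 1e-6)
})
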