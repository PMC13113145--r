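test_that("interface contacts respect the 4.5 Angstrom cutoff", {
  lig <- matrix(c(0, 0, 0), 1, 3)
  tgt <- rbind(c(4.4, 0, 0), c(4.6, 0, 0))
  expect_identical(interface_contacts(lig, tgt), 1L)
  expect_identical(interface_contacts(lig, tgt + 100), 0L)
  # the boundary itself counts (indicator is <=)
  expect_identical(interface_contacts(lig, matrix(c(4.5, 0, 0), 1, 3)), 1L)
})

test_that("contact counting equals the brute-force double loop", {
  brute <- function(a, b, cutoff = 4.5) {
    n <- 0L
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        if (sqrt(sum((a[i, ] - b[j, ])^2)) <= cutoff) n <- n + 1L
      }
    }
    n
  }
  torsdiff:::with_seed(12, {
    for (k in 1:50) {
      a <- matrix(stats::runif(3 * sample(2:15, 1), 0, 10), ncol = 3)
      b <- matrix(stats::runif(3 * sample(2:15, 1), 0, 10), ncol = 3)
      expect_identical(interface_contacts(a, b), brute(a, b))
    }
  })
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(radius_of_gyration(square), sqrt(0.5))
})

test_that("shape ratio distinguishes spheres from rods", {
  # regular tetrahedron: all principal radii equal
  simplex <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(shape_ratio(simplex), 1, tolerance = 1e-9)
  # collinear points cap at the configured maximum
  line <- cbind(seq(0, 10, length.out = 8), 0, 0)
  expect_equal(shape_ratio(line), 1e3)
  # stretching one axis never decreases the ratio
  torsdiff:::with_seed(3, {
    pts <- matrix(stats::rnorm(30), 10, 3)
    r0 <- shape_ratio(pts)
    stretched <- pts %*% diag(c(3, 1, 1))
    expect_gte(shape_ratio(stretched), r0)
  })
})

test_that("global-alignment identity matches the worked examples", {
  expect_equal(sequence_identity("ACDE", "ACDE"), 100)
  expect_equal(sequence_identity("ACDE", "ACDEFGHI"), 50)
  expect_equal(sequence_identity("AAAA", "CCCC"), 0)
  expect_equal(sequence_identity("ACDE", "AXDE"), 75)
})

test_that("alignment scores agree with an independent aligner", {
  nw_score <- function(a, b) {
    # recompute the optimal score (not identities) with Biostrings
    mat <- matrix(0, 20, 20, dimnames = list(torsdiff:::CANONICAL_AA,
                                             torsdiff:::CANONICAL_AA))
    diag(mat) <- 1
    Biostrings::pairwiseAlignment(a, b, type = "global",
                                  substitutionMatrix = mat,
                                  gapOpening = 0, gapExtension = 1)@score
  }
  my_score <- function(a, b) {
    # identities recovered from the reported percentage need the DP score;
    # recompute it directly from the DP recurrence for the check
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    sc <- matrix(0, n + 1, m + 1)
    sc[, 1] <- -(0:n); sc[1, ] <- -(0:m)
    for (i in 1:n) for (j in 1:m) {
      sc[i + 1, j + 1] <- max(sc[i, j] + (av[i] == bv[j]),
                              sc[i, j + 1] - 1, sc[i + 1, j] - 1)
    }
    sc[n + 1, m + 1]
  }
  torsdiff:::with_seed(21, {
    for (k in 1:10) {
      a <- paste(sample(torsdiff:::CANONICAL_AA, sample(5:12, 1), TRUE), collapse = "")
      b <- paste(sample(torsdiff:::CANONICAL_AA, sample(5:12, 1), TRUE), collapse = "")
      expect_equal(my_score(a, b), nw_score(a, b))
    }
  })
})

test_that("torsion windows classify ideal secondary structures", {
  h <- make_ideal_chain("helix", 10, seed = 1)
  s <- make_ideal_chain("strand", 10, seed = 1)
  lab_h <- assign_secondary(h$angles)
  ok <- h$angles$valid[, "phi"] & h$angles$valid[, "psi"]
  expect_true(all(lab_h[ok] == "H"))
  expect_true(all(lab_h[!ok] == "C"))
  expect_equal(helicity(h$angles), 1)
  expect_equal(rama_helix_fraction(h$angles), 1)
  expect_equal(helicity(s$angles), 0)
  expect_equal(rama_helix_fraction(s$angles), 0)
  expect_true(all(assign_secondary(s$angles)[ok] == "E"))
  # a half-helix half-strand table scores 0.5
  mixed <- angle_table(rbind(h$angles$angles[2:6, ], s$angles$angles[2:6, ]),
                       valid = matrix(TRUE, 10, 6))
  expect_equal(rama_helix_fraction(mixed), 0.5)
})

test_that("the Ramachandran histogram counts defined torsion pairs", {
  h <- make_ideal_chain("helix", 12, seed = 2)
  d <- rama_density(h$angles)
  expect_equal(dim(d), c(36, 36))
  expect_equal(sum(d), sum(h$angles$valid[, "phi"] & h$angles$valid[, "psi"]))
  expect_equal(max(d), sum(d))   # one ideal torsion pair, one occupied cell
})

test_that("clash counting excludes bonded neighbours", {
  h <- make_ideal_chain("helix", 12, seed = 5)
  expect_identical(clash_count(h$structure), 0L)
  expect_identical(clash_count(h$structure, cutoff = 0), 0L)
  # two distant residues forced onto each other clash once per atom pair
  tab <- random_angle_table(8, 3)
  st <- nerf_reconstruct(tab)
  st$coords[8, , ] <- st$coords[1, , ] + 0.5   # overlap residues 1 and 8
  expect_gt(clash_count(st), 0)
})

test_that("physicochemical metrics match published scales", {
  expect_equal(gravy("III"), 4.5)
  expect_equal(gravy("AR"), (1.8 - 4.5) / 2)
  expect_equal(aromaticity("FWYA"), 0.75)
  expect_equal(aromaticity("AAAA"), 0)
  # glycine pI sits at the midpoint of the terminal pKa values
  expect_equal(isoelectric_point("G"), (8.6 + 3.6) / 2, tolerance = 1e-6)
  # the returned pH is a true root of the net-charge function
  for (s in c("G", "KKDDE", "MKWVTF")) {
    expect_lt(abs(torsdiff:::net_charge(s, isoelectric_point(s))), 1e-4)
  }
  # acidic sequences have low pI, basic ones high
  expect_lt(isoelectric_point("DDEE"), 4.5)
  expect_gt(isoelectric_point("KKRR"), 10)
})

test_that("length-contact correlation handles exact and degenerate cases", {
  expect_equal(length_contact_correlation(data.frame(length = 1:5,
                                                     contacts = 2 * (1:5) + 1)), 1)
  expect_equal(length_contact_correlation(data.frame(length = 1:5,
                                                     contacts = -(1:5))), -1)
  r <- length_contact_correlation(data.frame(length = c(1, 2), contacts = c(1, 2)))
  expect_true(is.na(r))
  r2 <- length_contact_correlation(data.frame(length = rep(3, 5), contacts = 1:5))
  expect_true(is.na(r2))
  big <- torsdiff:::with_seed(8, data.frame(length = stats::rnorm(1000),
                                            contacts = stats::rnorm(1000)))
  expect_lt(abs(length_contact_correlation(big)), 0.1)
})

test_that("every metric is invariant under joint rigid transforms", {
  cx <- tiny_pair
  base <- evaluate_complex(cx$target$structure, cx$binder$structure,
                           binder_sequence = cx$binder$sequence,
                           native_sequence = cx$binder$sequence)
  for (seed in 1:3) {
    rot <- random_rotation(seed + 30)
    shift <- torsdiff:::with_seed(seed, stats::rnorm(3, sd = 20))
    moved <- evaluate_complex(
      transform_structure(cx$target$structure, rot, shift),
      transform_structure(cx$binder$structure, rot, shift),
      binder_sequence = cx$binder$sequence,
      native_sequence = cx$binder$sequence)
    for (col in names(base)) {
      expect_equal(moved[[col]], base[[col]], tolerance = 1e-6,
                   label = paste("metric", col, "after rigid transform"))
    }
  }
})

test_that("complex evaluation composes the suite and batches aggregate", {
  cx <- tiny_pair
  rep1 <- evaluate_complex(cx$target$structure, cx$binder$structure,
                           binder_sequence = cx$binder$sequence)
  expect_identical(rep1$contacts, cx$planted_contacts)
  expect_equal(rep1$helicity, 1)       # helix binder fixture
  expect_true(is.na(rep1$seq_identity))
  batch <- evaluate_batch(list(
    list(target = cx$target$structure, binder = cx$binder$structure,
         binder_sequence = cx$binder$sequence),
    list(target = cx$target$structure, binder = cx$binder$structure,
         binder_sequence = cx$binder$sequence,
         native_sequence = cx$binder$sequence)))
  expect_equal(nrow(batch$per_complex), 2)
  expect_true(all(c("mean", "median", "sd") %in% names(batch$aggregate)))
  expect_equal(batch$per_complex$seq_identity[2], 100)
})
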