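# Geometric hydrogen-bond counting.

test_that("the ideal linear dimer gives exactly one water-water bond", {
  f <- water_dimer_frame(d_OO = 0.28)
  hb <- find_hbonds(f)
  expect_equal(nrow(hb), 1L)
  expect_identical(hb$kind, "w-w")
  expect_equal(hb$distance_nm, 0.28, tolerance = 1e-9)
  expect_equal(hb$angle_deg, 0, tolerance = 1e-6)

  # beyond the cutoff: no bond
  expect_equal(nrow(find_hbonds(water_dimer_frame(d_OO = 0.5))), 0L)
})

test_that("frame validation enforces water topology and box size", {
  expect_error(md_frame(rbind(c(1, 1, 1), c(1.1, 1, 1)),
                        c("water_O", "water_H"), c(1, 1), c(2, 2, 2)),
               "exactly 1 O and 2 H")
  f <- water_dimer_frame()
  f$box <- c(0.5, 0.5, 0.5)
  expect_error(find_hbonds(f), "too small")
})

test_that("neighbor-list and brute-force searches agree on random periodic frames", {
  for (s in 1:50) {
    f <- random_water_frame(n = sample(20:120, 1), box_edge = 2, seed = s)
    a <- find_hbonds(f, method = "cell")
    b <- find_hbonds(f, method = "brute")
    expect_identical(a[c("donor_atom", "h_atom", "acceptor_atom")],
                     b[c("donor_atom", "h_atom", "acceptor_atom")])
  }
})

test_that("enlarging the cutoffs never removes a bond", {
  for (s in c(2, 9, 23)) {
    f <- random_water_frame(n = 80, box_edge = 2, seed = s)
    key <- function(hb) paste(hb$donor_atom, hb$h_atom, hb$acceptor_atom)
    base <- key(find_hbonds(f, r_cut = 0.35, angle_cut = 30))
    wide_r <- key(find_hbonds(f, r_cut = 0.45, angle_cut = 30))
    wide_a <- key(find_hbonds(f, r_cut = 0.35, angle_cut = 45))
    expect_true(all(base %in% wide_r))
    expect_true(all(base %in% wide_a))
  }
})

test_that("bond counting respects periodic boundaries", {
  # dimer straddling the box face: O at 0.05 and partner across the
  # boundary at 1.93 in a 2-nm box (minimum-image distance 0.12+0.28?)
  o1 <- c(0.05, 1, 1); o2 <- c(1.85, 1, 1)  # min-image O-O = 0.2 nm
  a <- 104.5 * pi / 180
  pos <- rbind(o1, o1 + 0.1 * c(-1, 0, 0),  # H pointing across the face
               o1 + 0.1 * c(cos(pi / 2), sin(pi / 2), 0),
               o2, o2 + 0.1 * c(cos(2), sin(2), 0) * c(0, 1, 1) +
                 c(0, 0.1, 0), o2 + c(0, -0.1, 0))
  f <- md_frame(pos, rep(c("water_O", "water_H", "water_H"), 2),
                rep(1:2, each = 3), c(2, 2, 2))
  hb <- find_hbonds(f)
  expect_gte(nrow(hb), 1L)
  expect_equal(hb$distance_nm[1L], 0.2, tolerance = 1e-9)
})

test_that("bulk coordination of a 2-donor/2-acceptor lattice is exactly 4", {
  f <- hb_lattice_frame(n_side = 4, d = 0.28)
  expect_equal(bulk_value(list(f)), 4.0, tolerance = 1e-12)

  # isolated waters have zero coordination
  iso <- random_water_frame(n = 4, box_edge = 4, seed = 1)
  expect_equal(bulk_value(list(iso)), 0)

  # lipid roles are rejected
  bad <- water_dimer_frame()
  bad$role[4L] <- "lipid_acceptor_heavy"
  bad$role[5:6] <- "other"
  bad$mol <- c(1L, 1L, 1L, 2L, 3L, 3L)
  expect_error(bulk_value(list(bad)), "pure water")
})

test_that("water-lipid bonds are classified and counted per water", {
  # water donating to a lipid head oxygen
  o <- c(1, 1, 1)
  a <- 104.5 * pi / 180
  pos <- rbind(o, o + c(0.1, 0, 0), o + 0.1 * c(cos(a), sin(a), 0),
               o + c(0.29, 0, 0))
  f <- md_frame(pos, c("water_O", "water_H", "water_H",
                       "lipid_acceptor_heavy"),
                c(1L, 1L, 1L, 2L), c(2, 2, 2))
  hb <- find_hbonds(f)
  expect_equal(nrow(hb), 1L)
  expect_identical(hb$kind, "w-l")
  wc <- mesowater:::.water_counts(f, hb)
  expect_equal(wc$wl, 1)
  expect_equal(wc$ww, 0)
})
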