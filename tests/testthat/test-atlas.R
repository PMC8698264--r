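make_two_lobe_labels <- function() {
  lab <- array(0L, c(10, 10, 10))
  lab[1:5, , ] <- 1L   # "frontal lobe"
  lab[6:10, , ] <- 2L  # "temporal lobe"
  label_volume(lab, label_names = c("1" = "frontal lobe",
                                    "2" = "temporal lobe"))
}

two_lobe_merge <- function() {
  lobe_merge_table(c("frontal lobe" = "frontal",
                     "temporal lobe" = "temporal"))
}

test_that("lobe proportions count merged-lobe voxels over N_ccm", {
  labs <- make_two_lobe_labels()
  inside <- box_mask(c(10, 10, 10), c(1, 4), c(1, 10), c(1, 10))
  prof <- lobe_proportions(inside, labs, two_lobe_merge())
  expect_equal(unname(prof$proportions["frontal"]), 1)
  expect_equal(sum(prof$proportions), prof$coverage)
  expect_equal(prof$coverage, 1)
  expect_identical(prof$dominant_lobe, "frontal")

  # straddling mask, 30/70 by voxel count, against a voxel-loop oracle
  straddle <- array(0L, c(10, 10, 10))
  straddle[3:7, 1:2, 1:10] <- 1L  # 3 planes in lobe 1, 2 planes in lobe 2... by x
  msk <- lesion_mask(straddle)
  prof2 <- lobe_proportions(msk, labs, two_lobe_merge())
  cnt <- c(frontal = 0, temporal = 0)
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    if (straddle[i, j, k] == 1L) {
      l <- if (labs$data[i, j, k] == 1L) "frontal" else "temporal"
      cnt[l] <- cnt[l] + 1
    }
  }
  expect_equal(unname(prof2$proportions["frontal"]),
               unname(cnt["frontal"] / sum(cnt)))
  expect_equal(unname(prof2$proportions["temporal"]),
               unname(cnt["temporal"] / sum(cnt)))
  expect_equal(unname(cnt["frontal"] / sum(cnt)), 0.6)
})

test_that("out-of-atlas voxels carry no lobe and close the budget to 1", {
  labs <- make_two_lobe_labels()
  labs$data[1:2, , ] <- 0L  # outside atlas
  msk <- box_mask(c(10, 10, 10), c(1, 10), c(1, 10), c(1, 10))
  prof <- lobe_proportions(msk, labs, two_lobe_merge())
  expect_lt(prof$coverage, 1)
  expect_equal(sum(prof$proportions) + (1 - prof$coverage), 1)
})

test_that("unmapped raw labels warn and count as none", {
  lab <- array(1L, c(4, 4, 4)); lab[1, 1, 1] <- 2L
  labs <- label_volume(lab, label_names = c("1" = "frontal lobe",
                                            "2" = "mystery region"))
  msk <- lesion_mask(array(1L, c(4, 4, 4)))
  expect_warning(
    prof <- lobe_proportions(msk, labs,
                             lobe_merge_table(c("frontal lobe" = "frontal"))),
    "mystery region")
  expect_equal(unname(prof$proportions["frontal"]), 63 / 64)
  expect_equal(prof$coverage, 63 / 64)
})

test_that("profiles are invariant to atlas integer recoding", {
  labs <- make_two_lobe_labels()
  msk <- random_mask(c(10, 10, 10), p = 0.4, seed = 77)
  prof1 <- lobe_proportions(msk, labs, two_lobe_merge())
  swapped <- array(0L, dim(labs$data))
  swapped[labs$data == 1L] <- 9L
  swapped[labs$data == 2L] <- 4L
  labs2 <- label_volume(swapped, label_names = c("9" = "frontal lobe",
                                                 "4" = "temporal lobe"))
  prof2 <- lobe_proportions(msk, labs2, two_lobe_merge())
  expect_equal(prof1$proportions, prof2$proportions)
  expect_identical(prof1$dominant_lobe, prof2$dominant_lobe)
})

test_that("lobe report renders shares in decreasing order", {
  prof <- structure(list(
    proportions = c(frontal = 0.06, temporal = 0, parietal = 0,
                    occipital = 0, limbic = 0.04, sublobar = 0.89,
                    cerebellum = 0, brainstem = 0)[MERGED_LOBES],
    coverage = 0.99, dominant_lobe = "sublobar", n_ccm = 100L),
    class = "lobe_profile")
  expect_identical(format_lobe_report(prof),
                   "sublobar (89%), frontal lobe (6%), limbic lobe (4%)")
})

test_that("location classes follow the lobe unions", {
  mk <- function(dom) {
    p <- setNames(numeric(8), MERGED_LOBES); p[dom] <- 1
    structure(list(proportions = p, coverage = 1, dominant_lobe = dom,
                   n_ccm = 10L), class = "lobe_profile")
  }
  bs <- assign_location_class(mk("brainstem"))
  expect_identical(bs$tentorial, "infratentorial")
  expect_true(is.na(bs$temporal_class))
  lim <- assign_location_class(mk("limbic"))
  expect_identical(lim$tentorial, "supratentorial")
  expect_identical(lim$temporal_class, "temporal")
  fr <- assign_location_class(mk("frontal"))
  expect_identical(fr$temporal_class, "extratemporal")
  cb <- assign_location_class(mk("cerebellum"))
  expect_identical(cb$tentorial, "infratentorial")

  empty <- structure(list(proportions = setNames(numeric(8), MERGED_LOBES),
                          coverage = 0, dominant_lobe = NA_character_,
                          n_ccm = 10L), class = "lobe_profile")
  expect_identical(assign_location_class(empty)$tentorial, "unclassified")
})

test_that("merge tables validate lobes and tie-breaks warn", {
  expect_error(lobe_merge_table(c("x" = "occiput")), "unknown merged")
  expect_error(lobe_merge_table(setNames("frontal", "")), "named")

  lab <- array(0L, c(4, 4, 4)); lab[1:2, , ] <- 1L; lab[3:4, , ] <- 2L
  labs <- label_volume(lab, label_names = c("1" = "temporal lobe",
                                            "2" = "frontal lobe"))
  msk <- lesion_mask(array(1L, c(4, 4, 4)))
  expect_warning(
    prof <- lobe_proportions(msk, labs,
                             lobe_merge_table(c("temporal lobe" = "temporal",
                                                "frontal lobe" = "frontal"))),
    "tied")
  expect_identical(prof$dominant_lobe, "frontal")  # fixed order breaks tie
})
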