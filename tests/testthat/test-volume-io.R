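test_that("volume round trips are lossless for data and spacing", {
  set.seed(101)
  for (i in 1:10) {
    v <- random_volume(shape = sample(8:20, 3, replace = TRUE),
                       spacing = round(stats::runif(3, 0.5, 3), 3))
    for (ext in c(".nii.gz", ".mha", ".mhd")) {
      f <- tempfile(fileext = ext)
      write_volume(v, f)
      r <- read_volume(f)
      expect_identical(r$data, v$data)
      # NIfTI headers store spacing as float32; MetaImage headers as text
      expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
    }
  }
})

test_that("NIfTI and MetaImage copies of one volume read back equal", {
  set.seed(7)
  v <- random_volume(c(12, 10, 9), spacing = c(1.25, 0.7, 0.7))
  f1 <- tempfile(fileext = ".nii.gz")
  f2 <- tempfile(fileext = ".mha")
  write_volume(v, f1)
  write_volume(v, f2)
  a <- read_volume(f1)
  b <- read_volume(f2)
  expect_equal(a$data, b$data)
  expect_equal(a$spacing, b$spacing, tolerance = 1e-6)
  expect_equal(a$spacing, c(1.25, 0.7, 0.7), tolerance = 1e-6)
})

test_that("I/O errors are reported distinctly", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "missing file")
  f <- tempfile(fileext = ".txt")
  writeLines("x", f)
  expect_error(read_volume(f), "unsupported format")
  expect_error(ct_volume(matrix(0, 4, 4)), "non-3D")
  expect_error(write_volume(random_volume(c(4, 4, 4)),
                            file.path(tempfile(), "no", "v.nii")),
               "unwritable")
})

test_that("mask reading validates the label vocabulary with a location", {
  m <- label_mask(array(0L, c(4, 4, 4)))
  m$data[2, 3, 1] <- 1L
  f <- tempfile(fileext = ".nii.gz")
  write_volume(m, f)
  ok <- read_mask(f)
  expect_s3_class(ok, "label_mask")
  expect_equal(sum(ok$data), 1L)
  bad <- m
  bad$labels <- c(0L, 1L, 2L)
  bad$data[2, 3, 1] <- 2L
  write_volume(bad, f)
  expect_error(read_mask(f, labels = c(0L, 1L)),
               "out-of-vocabulary label 2 at voxel \\(2, 3, 1\\)")
  allzero <- read_mask(f, labels = c(0L, 1L, 2L))
  expect_true(all(allzero$data %in% c(0L, 2L)))
})

make_manifest <- function(n, tumor, nontumor,
                          split = rep("train", n)) {
  manifest(data.frame(
    patient_id = sprintf("P%03d", seq_len(n)), split = split,
    image_path = sprintf("img%d.nii", seq_len(n)),
    mask_path = sprintf("msk%d.nii", seq_len(n)),
    has_tumor = tumor > 0, tumor_slices = tumor,
    nontumor_slices = nontumor))
}

test_that("manifest totals reproduce the dataset composition table", {
  # per-split patient and slice tallies of the source dataset
  n <- c(370, 90, 50)
  m <- make_manifest(sum(n),
                     tumor = c(rep(0, sum(n))), nontumor = rep(0, sum(n)),
                     split = rep(c("train", "test", "validation"), n))
  # distribute the printed split totals over patients (remainder on the first)
  put <- function(m, split, tumor, nontumor) {
    i <- which(m$split == split)
    k <- length(i)
    m$tumor_slices[i] <- diff(round(seq(0, tumor, length.out = k + 1)))
    m$nontumor_slices[i] <- diff(round(seq(0, nontumor, length.out = k + 1)))
    m
  }
  m <- put(m, "train", 14848, 20840)
  m <- put(m, "test", 4520, 4740)
  m <- put(m, "validation", 850, 900)
  tot <- manifest_totals(m)
  expect_equal(tot$patients, c(370, 90, 50, 510))
  expect_equal(tot$tumor_slices[tot$split == "total"], 20218)
  expect_equal(tot$nontumor_slices[tot$split == "total"], 26480)
  expect_equal(tot$all_slices[tot$split == "total"], 46698)
  expect_equal(tot$all_slices,
               c(35688, 9260, 1750, 46698))
})

test_that("manifest totals agree with a brute-force counting oracle", {
  set.seed(202)
  m <- make_manifest(1000, tumor = sample(0:50, 1000, TRUE),
                     nontumor = sample(0:80, 1000, TRUE),
                     split = sample(c("train", "test", "validation"),
                                    1000, TRUE))
  tot <- manifest_totals(m)
  # independent one-pass counting loop
  acc <- list(train = c(0, 0), test = c(0, 0), validation = c(0, 0))
  pats <- list(train = character(), test = character(),
               validation = character())
  for (i in seq_len(nrow(m))) {
    s <- m$split[i]
    acc[[s]] <- acc[[s]] + c(m$tumor_slices[i], m$nontumor_slices[i])
    pats[[s]] <- union(pats[[s]], m$patient_id[i])
  }
  for (s in names(acc)) {
    row <- tot[tot$split == s, ]
    expect_equal(row$tumor_slices, acc[[s]][1])
    expect_equal(row$nontumor_slices, acc[[s]][2])
    expect_equal(row$patients, length(pats[[s]]))
  }
  expect_equal(tot$all_slices[4], sum(m$tumor_slices + m$nontumor_slices))
  expect_error(manifest_totals(make_manifest(2, c(-1, 0), c(0, 0))),
               "non-negative")
})

test_that("patient-level splitting follows the fractions deterministically", {
  m <- make_manifest(10, tumor = rep(1, 10), nontumor = rep(1, 10))
  s1 <- split_dataset(m, c(0.8, 0.1, 0.1), seed = 7)
  expect_equal(unname(table(s1$split)[c("train", "validation", "test")]),
               c(8L, 1L, 1L), ignore_attr = TRUE)
  s2 <- split_dataset(m, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(s1$split, s2$split)
  expect_error(split_dataset(m, c(0.5, 0.5, 0.1)), "sum to 1")
  expect_error(split_dataset(make_manifest(2, 1:2, 1:2), c(0.8, 0.1, 0.1)),
               "fewer patients")
})

test_that("splitting never places a patient in two splits", {
  base <- make_manifest(17, tumor = rep(1, 17), nontumor = rep(1, 17))
  # duplicate records per patient to make leakage possible in principle
  m <- manifest(rbind(base, base, base))
  for (seed in 1:50) {
    s <- split_dataset(m, c(0.6, 0.2, 0.2), seed = seed)
    per_patient <- tapply(s$split, s$patient_id,
                          function(x) length(unique(x)))
    expect_true(all(per_patient == 1L))
  }
})

test_that("manifest CSV round-trips", {
  m <- make_manifest(5, tumor = 1:5, nontumor = 5:1)
  f <- tempfile(fileext = ".csv")
  write_manifest(m, f)
  r <- read_manifest(f)
  expect_equal(as.data.frame(r), as.data.frame(m))
})
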