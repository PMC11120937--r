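mk_pairs <- function(...) {
  # residue-pair summary rows: list(residue1, residue2, volume)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(residue1 = r[[1]], residue2 = r[[2]], class = "L1",
               area = as.numeric(r[[3]]) / 2, volume = as.numeric(r[[3]]),
               aowv = 2 * as.numeric(r[[3]]), n_atom_pairs = 1L,
               stringsAsFactors = FALSE)
  }))
}

test_that("mean and range matrices follow the absent-as-zero rule", {
  m1 <- mk_pairs(list("A:1:ALA", "A:5:ALA", 10))
  m2 <- mk_pairs(list("A:1:ALA", "A:5:ALA", 30))
  em <- ensemble_matrices(list(m1, m2), metric = "volume")
  expect_equal(em$mean["A:1:ALA", "A:5:ALA"], 20)
  expect_equal(em$range["A:1:ALA", "A:5:ALA"], 20)
  expect_true(isSymmetric(em$mean) && isSymmetric(em$range))

  # pair present in only one of two models
  em2 <- ensemble_matrices(list(m1, mk_pairs(list("A:1:ALA", "A:9:ALA", 4))),
                           metric = "volume")
  expect_equal(em2$mean["A:1:ALA", "A:5:ALA"], 5)
  expect_equal(em2$range["A:1:ALA", "A:5:ALA"], 10)

  em3 <- ensemble_matrices(list(m1), metric = "volume")
  expect_true(all(em3$range == 0))
})

test_that("N identical models give zero range and the single-model mean", {
  m1 <- mk_pairs(list("A:1:ALA", "A:5:ALA", 12), list("A:2:ALA", "A:5:ALA", 3))
  em <- ensemble_matrices(rep(list(m1), 7), metric = "volume")
  expect_true(all(em$range == 0))
  expect_equal(em$mean["A:2:ALA", "A:5:ALA"], 3)
})

test_that("frequency metric counts per-model presence", {
  m1 <- mk_pairs(list("A:1:ALA", "A:5:ALA", 10))
  m2 <- mk_pairs(list("A:1:ALA", "A:9:ALA", 10))
  em <- ensemble_matrices(list(m1, m2), metric = "frequency")
  expect_equal(em$mean["A:1:ALA", "A:5:ALA"], 0.5)
  expect_equal(em$range["A:1:ALA", "A:9:ALA"], 1)
})

test_that("flexible-contact flagging equals a brute-force scan", {
  expect_equal(nrow(flag_flexible_contacts(
    ensemble_matrices(list(mk_pairs(list("A:1:ALA", "A:5:ALA", 0))),
                      metric = "volume"), 0, 0)), 0)

  set.seed(21)
  models <- lapply(1:5, function(k) {
    mk_pairs(list("A:1:ALA", "A:5:ALA", runif(1, 0, 200)),
             list("A:2:ALA", "A:6:ALA", runif(1, 0, 200)),
             list("A:3:ALA", "A:7:ALA", runif(1, 0, 200)))
  })
  em <- ensemble_matrices(models, metric = "volume")
  got <- flag_flexible_contacts(em, 30, 100)
  # brute force over the upper triangle
  brute <- list()
  for (i in seq_along(em$residues)) for (j in seq_along(em$residues)) {
    if (j <= i) next
    if ((em$mean[i, j] > 0 || em$range[i, j] > 0) &&
        em$mean[i, j] >= 30 && em$range[i, j] >= 100) {
      brute[[length(brute) + 1]] <- c(em$residues[i], em$residues[j],
                                      em$range[i, j])
    }
  }
  expect_equal(nrow(got), length(brute))
  if (length(brute)) {
    ord <- order(-vapply(brute, function(b) as.numeric(b[3]), 0))
    expect_equal(got$residue1, vapply(brute[ord], `[`, "", 1))
  }
  # idempotent and threshold logic on a hand case
  one <- ensemble_matrices(list(mk_pairs(list("A:1:ARG", "A:9:GLU", 90)),
                                mk_pairs(list("A:1:ARG", "A:9:GLU", -30))),
                           metric = "volume")
  # mean 30, range 120
  fl <- flag_flexible_contacts(one, 30, 100)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$mean, 30)
  expect_equal(fl$range, 120)
  expect_identical(flag_flexible_contacts(one, 30, 100), fl)
})

test_that("ensemble matrices from the engine match per-model hand values", {
  atoms <- data.frame(name = c("O", "N"), resname = "GLY", chain = "A",
                      resseq = c(1, 5), x = c(0, 3.2), y = 0, z = 0,
                      element = c("O", "N"), stringsAsFactors = FALSE)
  ens <- tempfile(fileext = ".pdb")
  make_ensemble_pdb(atoms, list(c(0, 0, 0), function(a) {
    a$x[2] <- a$x[2] + 1.0; a
  }), ens)
  res <- analyze_file(ens, out_dir = NULL)
  vols <- vapply(res$models, function(m) m$pairs$volume[1], 0)
  expect_gt(vols[1], vols[2])   # larger separation, smaller overlap
  em <- ensemble_contacts(ens, metric = "volume")
  expect_equal(em$mean["A:1:GLY", "A:5:GLY"], mean(vols))
  expect_equal(em$range["A:1:GLY", "A:5:GLY"], max(vols) - min(vols))
})

test_that("heatmap rendering is deterministic and marks highlights", {
  m1 <- mk_pairs(list("A:1:ALA", "A:5:ALA", 10), list("A:2:ALA", "A:5:ALA", 40))
  em <- ensemble_matrices(list(m1, mk_pairs(list("A:1:ALA", "A:5:ALA", 200))),
                          metric = "volume")
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  render_heatmap(em, f1)
  render_heatmap(em, f2)
  expect_gt(file.size(f1), 0)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  f3 <- tempfile(fileext = ".png")
  hl <- data.frame(residue1 = "A:1:ALA", residue2 = "A:5:ALA")
  render_heatmap(em, f3, highlight = hl)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("atom scatter writes one image per model, waters excluded", {
  atoms <- rbind(toy_tripeptide_atoms(),
                 data.frame(name = "O", resname = "HOH", chain = "A",
                            resseq = 90, x = 9, y = 9, z = 0, element = "O",
                            stringsAsFactors = FALSE))
  ens <- tempfile(fileext = ".pdb")
  make_ensemble_pdb(atoms, list(c(0, 0, 0), c(1, 0, 0)), ens)
  st <- parse_structure(ens)
  f <- tempfile(fileext = ".png")
  paths <- render_atom_scatter(st, f)
  expect_length(paths, 2)
  expect_true(all(file.exists(paths)))
  m0 <- st$models[[1]]
  m0$is_water <- TRUE   # nothing left to draw
  expect_error(render_atom_scatter(m0, tempfile(fileext = ".png")),
               "no solute")
})

test_that("matrix CSV export round-trips", {
  em <- ensemble_matrices(list(mk_pairs(list("A:1:ALA", "A:5:ALA", 10))),
                          metric = "volume")
  f <- tempfile(fileext = ".csv")
  write_matrix_csv(em, f, "mean")
  back <- as.matrix(utils::read.csv(f, row.names = 1, check.names = FALSE))
  expect_equal(back, em$mean)
})
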