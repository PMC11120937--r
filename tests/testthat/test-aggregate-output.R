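test_that("cutoff filter is boundary-inclusive and validates arguments", {
  cc <- data.frame(area = c(1, 1, 1), volume = c(0.1, 0.25, 0.9))
  expect_equal(nrow(apply_cutoff(cc, 0, 0.25)), 2)
  expect_equal(apply_cutoff(cc, 0, 0), cc)
  expect_error(apply_cutoff(cc, -1, 0), "non-negative")

  set.seed(3)
  rnd <- data.frame(area = runif(40, 0, 2), volume = runif(40, 0, 1))
  got <- apply_cutoff(rnd, 0.5, 0.25)
  hand <- rnd[rnd$area >= 0.5 & rnd$volume >= 0.25, ]
  expect_equal(got, hand)
})

test_that("residue-pair totals are exact sums, stable under permutation", {
  mk <- function(s1, s2, r1, r2, a, v, w) {
    data.frame(serial1 = s1, serial2 = s2, residue1 = r1, residue2 = r2,
               area = a, volume = v, aowv = w, class = "S",
               stringsAsFactors = FALSE)
  }
  cc <- rbind(mk(1, 6, "A:1:ALA", "A:2:ALA", 1.0, 1.25, 2.5),
              mk(2, 7, "A:1:ALA", "A:2:ALA", 0.5, 2.50, 5.0),
              mk(3, 11, "A:1:ALA", "A:3:ALA", 2.0, 0.70, 1.4))
  tot <- residue_pair_totals(cc)
  expect_equal(nrow(tot), 2)
  expect_identical(tot$volume[1], 1.25 + 2.50)
  expect_identical(tot$area[1], 1.5)
  expect_equal(tot$n_atom_pairs, c(2L, 1L))

  perm <- cc[c(3, 1, 2), ]
  expect_identical(residue_pair_totals(perm), tot)
  expect_equal(nrow(residue_pair_totals(cc[0, ])), 0)
})

test_that("residue summaries split covalent from non-covalent disjointly", {
  m <- assigned_model(toy_tripeptide_atoms())
  eng <- compute_model_contacts(m, with_sasa = TRUE)
  rs <- residue_summaries(m, eng$contacts, eng$atom_sasa)
  expect_equal(nrow(rs), 3)
  cov <- eng$contacts[eng$contacts$covalent, ]
  r1 <- rs$resid[1]
  hand_cova <- sum(cov$area[cov$residue1 == r1 | cov$residue2 == r1])
  expect_equal(rs$cova_area[1], hand_cova)
  nc <- eng$contacts[!eng$contacts$covalent, ]
  hand_nc <- sum(nc$area[nc$residue1 == r1 | nc$residue2 == r1])
  expect_equal(rs$nc_area[1], hand_nc)
  expect_equal(rs$sasa,
               as.numeric(tapply(eng$atom_sasa, solute_atoms(m)$resid,
                                 sum)[rs$resid]))
})

test_that("flag/column contract holds for all -a/-w/-s combinations", {
  m <- assigned_model(toy_tripeptide_atoms())
  eng <- compute_model_contacts(m, with_sasa = TRUE)
  pairs <- residue_pair_totals(eng$contacts)
  rs <- residue_summaries(m, eng$contacts, eng$atom_sasa)
  base_all <- c("Residue1", "Atom1", "Type1", "Residue2", "Atom2", "Type2",
                "Distance", "Area")
  for (a in c(FALSE, TRUE)) for (w in c(FALSE, TRUE)) for (s in c(FALSE, TRUE)) {
    fl <- list(a = a, w = w, s = s, z = FALSE)
    f1 <- tempfile(fileext = ".csv")
    write_all_csv(eng$contacts, f1, fl)
    hdr <- strsplit(readLines(f1, n = 1), ",")[[1]]
    want <- c(base_all, if (!s) "Volume", if (w) "AOWV", "Contact", "Class")
    expect_identical(hdr, want)

    f2 <- tempfile(fileext = ".csv")
    write_sum_csv(rs, f2, fl)
    hdr2 <- strsplit(readLines(f2, n = 1), ",")[[1]]
    want2 <- c("Residue", "Phi", "Psi", "Cova_Area", "NC_Area",
               if (!s) c("Cova_Volu", "NC_Volu"), if (a) "SASA",
               if (w) c("Cova_AOWV", "NC_AOWV"))
    expect_identical(hdr2, want2)

    f3 <- tempfile(fileext = ".csv")
    write_res_csv(pairs, f3, fl)
    hdr3 <- strsplit(readLines(f3, n = 1), ",")[[1]]
    expect_identical(hdr3, c("Residue1", "Residue2", "Class", "Area",
                             if (!s) "Volume", if (w) "AOWV"))
  }
})

test_that("written CSVs round-trip at the serialized precision", {
  m <- assigned_model(toy_tripeptide_atoms())
  eng <- compute_model_contacts(m)
  f <- tempfile(fileext = ".csv")
  write_all_csv(eng$contacts, f, list())
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(back), nrow(eng$contacts))
  expect_equal(back$Volume, round(eng$contacts$volume, 4))
  expect_equal(back$Area, round(eng$contacts$area, 4))
  expect_identical(back$Residue1, eng$contacts$residue1)
})

test_that("gzip outputs read back to identical tables", {
  m <- assigned_model(toy_tripeptide_atoms())
  eng <- compute_model_contacts(m)
  pairs <- residue_pair_totals(eng$contacts)
  f <- tempfile(fileext = ".csv")
  write_res_csv(pairs, f, list(z = TRUE))
  expect_true(file.exists(paste0(f, ".gz")))
  gz <- utils::read.csv(gzfile(paste0(f, ".gz")), check.names = FALSE)
  f2 <- tempfile(fileext = ".csv")
  write_res_csv(pairs, f2, list())
  plain <- utils::read.csv(f2, check.names = FALSE)
  expect_identical(gz, plain)
})

test_that("non-standard residues are suffixed and UNDEF columns appear", {
  atoms <- rbind(toy_tripeptide_atoms(),
                 data.frame(name = "FE", resname = "HEM", chain = "A",
                            resseq = 9, x = 2.5, y = 3.0, z = 0.5,
                            element = "FE", stringsAsFactors = FALSE))
  atoms$het <- atoms$resname == "HEM"
  m <- assigned_model(atoms)
  eng <- compute_model_contacts(m)
  rs <- residue_summaries(m, eng$contacts, NULL)
  f <- tempfile(fileext = ".csv")
  write_sum_csv(rs, f, list())
  lines <- readLines(f)
  expect_true(any(grepl("HEM_", lines)))
  expect_true(grepl("UNDEF_Area,UNDEF_Volu", lines[1]))
  # undefined dihedrals serialize as empty fields
  expect_match(lines[2], "^A:1:ALA,,")
})

test_that("CLI writes per-model subfolders and batch output folders", {
  ens <- tempfile(fileext = ".pdb")
  make_ensemble_pdb(toy_tripeptide_atoms(), list(c(0, 0, 0), c(0.3, 0, 0)), ens)
  out <- tempfile()
  expect_identical(run_cli(c(ens, "-o", out)), 0L)
  base <- sub("\\.pdb$", "", basename(ens))
  for (k in 1:2) {
    dir <- file.path(out, base, paste0("model_", k))
    expect_true(file.exists(file.path(dir, paste0(base, "_ALL.csv"))))
    expect_true(file.exists(file.path(dir, paste0(base, "_SUM.csv"))))
    expect_true(file.exists(file.path(dir, paste0(base, "_RES.csv"))))
  }

  d <- tempfile(); dir.create(d)
  for (nm in c("x1.pdb", "x2.pdb", "x3.pdb")) {
    make_two_atom_pdb(c("O", "N"), 3.0, file.path(d, nm))
  }
  out2 <- tempfile()
  expect_identical(run_cli(c(d, "-o", out2)), 0L)
  expect_equal(sort(list.dirs(out2, recursive = FALSE, full.names = FALSE)),
               c("x1", "x2", "x3"))
})

test_that("thread count never changes output bytes", {
  p <- toy_tripeptide_pdb()
  out1 <- tempfile(); out4 <- tempfile()
  expect_identical(run_cli(c(p, "-o", out1, "-t", "1", "-a", "-w")), 0L)
  expect_identical(run_cli(c(p, "-o", out4, "-t", "4", "-a", "-w")), 0L)
  f1 <- sort(list.files(out1, recursive = TRUE, full.names = TRUE))
  f4 <- sort(list.files(out4, recursive = TRUE, full.names = TRUE))
  expect_equal(basename(f1), basename(f4))
  for (k in seq_along(f1)) {
    expect_identical(readBin(f1[k], "raw", file.size(f1[k])),
                     readBin(f4[k], "raw", file.size(f4[k])))
  }
})

test_that("CLI rejects bad invocations with a nonzero status", {
  expect_identical(suppressMessages(run_cli(character(0))), 2L)
  expect_identical(suppressMessages(run_cli(c("nosuch.pdb"))), 2L)
  p <- toy_tripeptide_pdb()
  expect_identical(suppressMessages(run_cli(c(p, "--bogus"))), 2L)
  expect_identical(suppressMessages(run_cli(c(p, "-c", "-1"))), 2L)
})

test_that("cutoff and surface flags propagate through the CLI", {
  p <- toy_tripeptide_pdb()
  out <- tempfile()
  expect_identical(run_cli(c(p, "-o", out, "-c", "0.5,0.25", "-s", "-z")), 0L)
  base <- sub("\\.pdb$", "", basename(p))
  all_gz <- file.path(out, base, paste0(base, "_ALL.csv.gz"))
  expect_true(file.exists(all_gz))
  tab <- utils::read.csv(gzfile(all_gz), check.names = FALSE)
  expect_false("Volume" %in% colnames(tab))
  expect_true(all(tab$Area >= 0.5))
})
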