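test_that("identical seeds give bit-identical fields and ground truth", {
  cm <- cell_model("M2A", p_break = 0.3, p_transloc_given_break = 0.5)
  a <- simulate_field(cm, 4, imaging = test_imaging(), seed = 11)
  b <- simulate_field(cm, 4, imaging = test_imaging(), seed = 11)
  expect_identical(a$truth, b$truth)
  expect_identical(a$field$stacks, b$field$stacks)
  c <- simulate_field(cm, 4, imaging = test_imaging(), seed = 12)
  expect_false(identical(a$truth$spots$x, c$truth$spots$x))
})

test_that("zero breakage probability yields only intact alleles", {
  sim <- simulate_field(cell_model(p_break = 0), 30,
                        seed = 5, render = FALSE,
                        imaging = imaging_config(field_shape_px = c(384, 384)))
  expect_true(all(sim$truth$alleles$state == "intact"))
  tt <- truth_tables(sim)
  ev <- call_events(tt$nuclei, tt$spots)
  # every Red signal stays proximal to a Green signal: no breakage calls
  expect_true(all(ev$alleles$rg_min <= 4))
  expect_equal(sum(ev$nuclei$n_breakage_events), 0L)
})

test_that("ground truth conserves spot counts and the event hierarchy", {
  cm <- cell_model("mix", n_alleles_A = 3, n_alleles_B = 2,
                   p_break = 0.5, p_transloc_given_break = 0.5)
  sim <- simulate_field(cm, 25, seed = 7, render = FALSE,
                        imaging = imaging_config(field_shape_px = c(384, 384)))
  sp <- sim$truth$spots
  counts <- table(sp$cell_id, sp$channel)
  expect_true(all(counts[, "Red"] == 3))
  expect_true(all(counts[, "Green"] == 3))
  expect_true(all(counts[, "FarRed"] == 2))
  # translocated alleles are a subset of broken ones by construction:
  # the generator never marks an unbroken allele translocated
  st <- sim$truth$alleles$state
  expect_true(all(st %in% c("intact", "broken", "translocated")))
  # a FarRed spot relocated to a gene-A allele implies that allele is not
  # intact
  fr <- sp[sp$channel == "FarRed" & grepl("^A", sp$allele_id), ]
  if (nrow(fr)) {
    key <- paste(fr$cell_id, fr$allele_id)
    akey <- paste(sim$truth$alleles$cell_id, sim$truth$alleles$allele_id)
    expect_true(all(sim$truth$alleles$state[match(key, akey)] ==
                      "translocated"))
  }
})

test_that("all ground-truth spots lie inside their parent nucleus", {
  cm <- cell_model("mix", p_break = 0.5, p_transloc_given_break = 1)
  sim <- simulate_field(cm, 20, seed = 9, render = FALSE,
                        imaging = imaging_config(field_shape_px = c(384, 384)))
  cells <- sim$truth$cells
  sp <- sim$truth$spots
  for (i in seq_len(nrow(sp))) {
    ce <- cells[cells$cell_id == sp$cell_id[i], ]
    ct <- cos(ce$theta); st <- sin(ce$theta)
    u <- ((sp$x[i] - ce$x) * ct + (sp$y[i] - ce$y) * st) / ce$a_px
    v <- (-(sp$x[i] - ce$x) * st + (sp$y[i] - ce$y) * ct) / ce$b_px
    expect_lt(u^2 + v^2, 1)
  }
})

test_that("realized breakage frequency matches the binomial prescription", {
  # p_break = 0.5 on two alleles: P(>=1 broken) = 0.75; with 2000 cells the
  # realized fraction must fall in the exact central 99% binomial band
  cm <- cell_model("half", n_alleles_A = 2, n_alleles_B = 2, p_break = 0.5)
  st <- simulate_truth_only(cm, 2000, seed0 = 3000)
  key <- paste(st$alleles$field_id, st$alleles$cell_id)
  frac <- mean(tapply(st$alleles$state != "intact", key, any))
  band <- stats::qbinom(c(0.005, 0.995), 2000, 0.75) / 2000
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("over-dense placement fails with an informative error", {
  expect_error(
    simulate_field(cell_model(), 200,
                   imaging = imaging_config(field_shape_px = c(96, 96)),
                   seed = 1, render = FALSE),
    "dense")
})

test_that("simulate_experiment writes a parseable two-condition dataset", {
  out <- file.path(tempdir(), "ds1")
  unlink(out, recursive = TRUE)
  conds <- list(
    list(label = "BC_000001_M2A_GFP_ALK_UN",
         cell_model = cell_model("M2A", p_break = 0), n_cells = 6),
    list(label = "BC_000001_M2A_GFP_ALK_IR",
         cell_model = cell_model("M2A", p_break = 0.02), n_cells = 6))
  man <- simulate_experiment(conds, out, imaging = test_imaging(),
                             seed = 21, cells_per_field = 3)
  expect_setequal(names(man), vapply(conds, `[[`, "", "label"))
  for (co in conds) {
    d <- file.path(out, co$label)
    expect_true(dir.exists(d))
    expect_length(discover_fields(d), 2L)
    md <- parse_metadata(co$label)
    expect_equal(md$cell_line, "M2A")
    al <- read_ba_table(file.path(d, "ground_truth_alleles.tsv"))
    expect_equal(nrow(al), 6 * 3)
  }
  un <- read_ba_table(file.path(out, conds[[1]]$label,
                                "ground_truth_alleles.tsv"))
  expect_true(all(un$state == "intact"))
  # refusal to overwrite silently
  expect_error(simulate_experiment(conds, out, imaging = test_imaging(),
                                   seed = 21), "overwrite")
  unlink(out, recursive = TRUE)
})

test_that("an empty condition list produces an empty dataset, not an error", {
  out <- file.path(tempdir(), "ds-empty")
  unlink(out, recursive = TRUE)
  man <- simulate_experiment(list(), out, seed = 1)
  expect_length(man, 0L)
  expect_true(dir.exists(out))
  unlink(out, recursive = TRUE)
})

test_that("dataset generation is reproducible byte for byte", {
  conds <- list(list(label = "BC_000002_M2A_GFP_ALK_UN",
                     cell_model = cell_model(), n_cells = 3))
  o1 <- file.path(tempdir(), "dsr1"); o2 <- file.path(tempdir(), "dsr2")
  unlink(c(o1, o2), recursive = TRUE)
  simulate_experiment(conds, o1, imaging = test_imaging(), seed = 33,
                      cells_per_field = 3)
  simulate_experiment(conds, o2, imaging = test_imaging(), seed = 33,
                      cells_per_field = 3)
  f1 <- sort(list.files(o1, recursive = TRUE, pattern = "\\.tif$",
                        full.names = TRUE))
  f2 <- sort(list.files(o2, recursive = TRUE, pattern = "\\.tif$",
                        full.names = TRUE))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(o1, o2), recursive = TRUE)
})
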