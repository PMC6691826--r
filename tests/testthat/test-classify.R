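free3 <- function() wl_table(c(-1, -1, -1))
bound3 <- function(v) wl_table(v, protein_present = TRUE)

test_that("sign patterns distinguish flipped, same and ambiguous protons", {
  pat <- sign_pattern(free3(), bound3(c(1, -0.5, 0.02)))
  expect_equal(unname(pat), c("flipped", "same", "ambiguous"))
  # floor is relative to the reference magnitude
  pat2 <- sign_pattern(free3(), bound3(c(1, -0.5, 0.06)), noise_floor = 0.05)
  expect_equal(unname(pat2["H3"]), "flipped")
})

test_that("the four canonical fixtures classify as Cases 1-4", {
  fx <- make_case_fixtures()
  for (nm in names(fx)) {
    fs <- wlogsy_factors(fx[[nm]]$free, fx[[nm]]$bound)
    pat <- sign_pattern(fx[[nm]]$free, fx[[nm]]$bound)
    cl <- classify_case(pat, fs)
    expect_equal(cl$value, fx[[nm]]$case, label = nm)
  }
})

test_that("classification is invariant under global sign inversion", {
  fx <- make_case_fixtures()
  for (nm in names(fx)) {
    flip_free <- fx[[nm]]$free;  flip_free$intensity <- -flip_free$intensity
    flip_bound <- fx[[nm]]$bound; flip_bound$intensity <- -flip_bound$intensity
    fs <- wlogsy_factors(flip_free, flip_bound)
    cl <- classify_case(sign_pattern(flip_free, flip_bound), fs)
    expect_equal(cl$value, fx[[nm]]$case, label = nm)
  }
})

test_that("the case predicates partition random non-degenerate inputs", {
  set.seed(7)
  for (rep in 1:50) {
    f <- -stats::runif(4, 0.3, 1)
    b <- sample(c(-1, 1), 4, replace = TRUE) * stats::runif(4, 0.3, 1)
    fs <- wlogsy_factors(wl_table(f), bound3(b))
    pat <- sign_pattern(wl_table(f), bound3(b))
    cl <- classify_case(pat, fs)
    expect_true(cl$value %in% 1:4)
    # predicate consistency
    if (all(pat == "flipped")) expect_true(cl$value %in% 1:2)
    else if (all(pat == "same")) expect_equal(cl$value, 4L)
    else expect_equal(cl$value, 3L)
  }
})

test_that("all-ambiguous input refuses classification with advice", {
  expect_error(classify_case(c(H1 = "ambiguous", H2 = "ambiguous"),
                             wlogsy_factors(free3(), bound3(c(1, 1, 1)))),
               "protein concentration|scans", class = "wlogsy_data_error")
})

test_that("exposure calls follow the smallest-factor-is-exposed rule", {
  fs2 <- wlogsy_factors(free3(), bound3(c(1, 1, 0.5)))
  cl2 <- classify_case(sign_pattern(free3(), bound3(c(1, 1, 0.5))), fs2)
  expect_equal(unname(call_exposure(cl2, fs2)),
               c("buried", "buried", "exposed"))

  fs4 <- wlogsy_factors(free3(), bound3(c(-1, -1, -0.5)))
  cl4 <- classify_case(sign_pattern(free3(), bound3(c(-1, -1, -0.5))), fs4)
  expect_equal(unname(call_exposure(cl4, fs4)),
               c("exposed", "exposed", "buried"))

  fs1 <- wlogsy_factors(free3(), bound3(c(1, 1, 1)))
  cl1 <- classify_case(sign_pattern(free3(), bound3(c(1, 1, 1))), fs1)
  expect_equal(unname(call_exposure(cl1, fs1)), rep("no_call", 3))

  # intermediate band between the cuts
  expect_equal(unname(call_exposure(cl2, fs2, exposed_cut = 60,
                                    buried_cut = 95))[3], "intermediate")
})

test_that("exposure calls are order-consistent with factors", {
  set.seed(11)
  for (rep in 1:30) {
    b <- sample(c(-1, 1), 5, replace = TRUE) * stats::runif(5, 0.2, 1)
    fs <- wlogsy_factors(wl_table(rep(-1, 5)), bound3(b))
    cl <- classify_case(sign_pattern(wl_table(rep(-1, 5)), bound3(b)), fs)
    ex <- call_exposure(cl, fs)
    if (cl$value == 1L) next
    pe <- fs$normalized_pct[ex == "exposed"]
    pb <- fs$normalized_pct[ex == "buried"]
    if (length(pe) && length(pb)) expect_lt(max(pe), min(pb))
  }
})

test_that("epitope maps assemble, reconcile with STD and serialise", {
  std <- intensity_table(c(1, 1, 0.70), proton_id = paste0("H", 1:3),
                         experiment = "STD", protein_present = TRUE)
  oned <- intensity_table(c(1, 1, 1), proton_id = paste0("H", 1:3),
                          experiment = "ONED", protein_present = TRUE)
  map <- map_epitope(free3(), bound3(c(1, 1, 0.5)), std = std, oned = oned)
  expect_s3_class(map, "epitope_map")
  expect_equal(map$case$value, 2L)
  expect_true(all(map$table$std_agrees))   # 75 vs 70 within 20 points

  # identical factor sets: zero disagreements
  fs <- wlogsy_factors(free3(), bound3(c(1, 1, 0.5)))
  map2 <- reconcile_std(map, fs)
  expect_true(all(map2$table$std_agrees))

  # STD-only exposure triggers the mixing-time recommendation
  std2 <- intensity_table(c(1, 0.3, 1), proton_id = paste0("H", 1:3),
                          experiment = "STD", protein_present = TRUE)
  map3 <- map_epitope(free3(), bound3(c(1, 1, 1)), std = std2, oned = oned)
  expect_match(paste(map3$notes, collapse = " "), "mixing time",
               ignore.case = TRUE)

  # WaterLOGSY proton absent from STD: bound-water note
  fs_partial <- std_factors(
    intensity_table(c(1, 0.5), proton_id = c("H1", "H2"),
                    experiment = "STD", protein_present = TRUE),
    intensity_table(c(1, 1), proton_id = c("H1", "H2"),
                    experiment = "ONED", protein_present = TRUE))
  map4 <- reconcile_std(map_epitope(free3(), bound3(c(1, 1, 0.5))), fs_partial)
  expect_match(paste(map4$notes, collapse = " "), "bound water")

  paths <- write_epitope_report(map, file.path(withr::local_tempdir(), "ep"),
                                markdown = TRUE)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(js$case, 2L)
  expect_equal(js$protons$exposure, c("buried", "buried", "exposed"))
})

test_that("analogue comparison reports factor shifts and verdicts", {
  fs_a <- wlogsy_factors(free3(), bound3(c(1, 1, 0.5)))   # 100,100,75
  fs_b <- wlogsy_factors(free3(), bound3(c(1, 1, 1)))     # 100,100,100
  same <- compare_analogues(fs_a, fs_a)
  expect_equal(same$table$difference, c(0, 0, 0))
  expect_equal(same$verdict, "binding mode unchanged")

  cmp <- compare_analogues(fs_a, fs_b)
  expect_equal(cmp$table$difference[3], 25)
  expect_equal(cmp$verdict, "binding mode altered")
  expect_equal(cmp$changed, "H3")

  expect_warning(
    part <- compare_analogues(fs_a, fs_b,
                              mapping = c(H1 = "H1", H9 = "H2")),
    "unmapped")
  expect_equal(part$table$proton_a, "H1")
  expect_error(suppressWarnings(
    compare_analogues(fs_a, fs_b, mapping = c(H8 = "H9"))),
    "no comparable protons", class = "wlogsy_data_error")
})
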