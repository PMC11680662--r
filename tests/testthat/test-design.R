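test_that("stimulus set has the full hub/neighbor structure", {
  st <- build_stimulus_set()
  expect_equal(nrow(st), 42L)
  expect_equal(sum(st$role == "hub"), 6L)
  expect_equal(sum(st$lexicality == "nonword"), 18L)
  for (nb in 0:5) {
    grp <- st[st$neighborhood_id == nb, ]
    expect_equal(nrow(grp), 7L)
    expect_equal(sum(grp$role == "hub"), 1L)
    hub <- grp[grp$role == "hub", ]
    expect_equal(hub$changed_position, "none")
    expect_equal(hub$overlap_class, "full")
    for (lex in c("word", "nonword")) {
      nbr <- grp[grp$role == "neighbor" & grp$lexicality == lex, ]
      expect_setequal(nbr$changed_position, c("onset", "vowel", "coda"))
    }
    # coda change leaves the CV shared: one word + one nonword per hood
    cv <- grp[grp$overlap_class == "shares_CV", ]
    expect_equal(nrow(cv), 2L)
    expect_setequal(cv$lexicality, c("word", "nonword"))
  }
  expect_equal(
    unname(c(onset = "shares_VC", vowel = "shares_frame",
             coda = "shares_CV")[st$changed_position[st$role == "neighbor"]]),
    st$overlap_class[st$role == "neighbor"])
  expect_identical(st, build_stimulus_set())
})

test_that("training-item selection respects conditions and holds out the hub", {
  st <- build_stimulus_set()
  w <- select_training_items(st, 0, "words_only")
  expect_equal(nrow(w), 3L)
  expect_true(all(w$lexicality == "word" & w$role == "neighbor"))
  n <- select_training_items(st, 0, "nonwords_only")
  expect_true(all(n$lexicality == "nonword"))
  cv <- select_training_items(st, 0, "cv_overlap")
  expect_equal(nrow(cv), 2L)
  expect_true(all(cv$changed_position == "coda"))
  vc <- select_training_items(st, 3, "vc_overlap")
  expect_true(all(vc$changed_position == "onset"))
  for (nb in 0:5) for (cond in decoding_conditions())
    expect_false(any(select_training_items(st, nb, cond)$role == "hub"))
  expect_error(select_training_items(st, 0, "mixed"), "unknown condition")
  expect_error(select_training_items(st, 9, "words_only"),
               "unknown neighborhood")
})

test_that("schedules satisfy block, talker and hub-adjacency constraints", {
  cfg <- design_config(n_subjects = 2L)
  st <- build_stimulus_set(cfg)
  sch <- make_schedule(cfg, seed = 5L, st)
  hubs <- st$item_id[st$role == "hub"]
  for (sj in unique(sch$subject_id)) {
    s <- sch[sch$subject_id == sj, ]
    expect_equal(length(unique(s$block_index)), 16L)
    expect_true(all(table(s$block_index) == 48L))
    # talkers: 2 blocks each, non-consecutive, 96 trials
    tb <- unique(s[, c("block_index", "talker_id")])
    tb <- tb[order(tb$block_index), ]
    expect_true(all(table(tb$talker_id) == 2L))
    expect_false(any(tb$talker_id[-1] == tb$talker_id[-16]))
    expect_true(all(table(s$talker_id) == 96L))
    for (bl in unique(s$block_index)) {
      b <- s[s$block_index == bl, ]
      expect_true(all(table(b$item_id[b$item_id %in% hubs]) == 2L))
      adjacent_same <- b$item_id[-1] == b$item_id[-48] &
        b$item_id[-1] %in% hubs
      expect_false(any(adjacent_same))
    }
  }
  expect_true(all(sch$presentation_number %in% 1:2))
})

test_that("schedules are seed-reproducible and seed-sensitive", {
  cfg <- design_config(n_subjects = 1L)
  s1 <- make_schedule(cfg, seed = 11L)
  s2 <- make_schedule(cfg, seed = 11L)
  s3 <- make_schedule(cfg, seed = 12L)
  expect_identical(s1, s2)
  expect_false(identical(s1$item_id, s3$item_id))
  tmp <- tempfile(fileext = ".tsv")
  write_schedule(s1, tmp)
  expect_equal(as.data.frame(read_schedule(tmp)), as.data.frame(s1))
})

test_that("design config validates and round-trips through YAML", {
  expect_error(design_config(stim_offset = -10), "epoch_start")
  expect_error(design_config(sample_rate = 0), "sample_rate")
  cfg <- design_config(n_subjects = 3L, sample_rate = 250)
  tmp <- tempfile(fileext = ".yaml")
  write_design_config(cfg, tmp)
  expect_equal(read_design_config(tmp), cfg)
  expect_equal(cfg$n_blocks, 2L * cfg$n_talkers)
})
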