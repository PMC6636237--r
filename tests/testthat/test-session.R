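test_that("new sessions start empty with the standard clinical context", {
  s <- new_session(demo_kb(), "case_44")
  expect_equal(s$clinical_info, "moderate pelvic pain and positive pregnancy test")
  expect_length(s$annotations, 0L)
  expect_identical(identified_signs(s), character())
  expect_identical(absent_signs(s), character())
  expect_identical(completed_views(s), character())

  s2 <- new_session(demo_kb(), "case_45", clinical_info = "custom context")
  expect_equal(s2$clinical_info, "custom context")
})

test_that("sessions are isolated: mutating one leaves the other unchanged", {
  kb <- fig5_kb()
  s1 <- new_session(kb, "a")
  s2 <- new_session(kb, "b")
  add_image(s1, image_annotation("img1", "epo:echographic_view_i",
                                 signs_present = "epo:sign_A"))
  expect_length(s1$annotations, 1L)
  expect_length(s2$annotations, 0L)
})

test_that("annotations validate keywords against the knowledge base", {
  s <- new_session(fig5_kb(), "c")
  expect_error(
    add_image(s, image_annotation("i1", "epo:echographic_view_i",
                                  signs_present = "epo:undeclared")),
    "unknown sign: epo:undeclared")
  # kind mismatch: a disorder where a sign is expected
  expect_error(
    add_image(s, image_annotation("i1", "epo:echographic_view_i",
                                  signs_present = "epo:disorder_1")),
    "unknown sign")
  # a sign used as a view
  expect_error(
    add_image(s, image_annotation("i1", "epo:sign_A")),
    "unknown echographic_view")
  expect_error(image_annotation("i1", "epo:echographic_view_i",
                                signs_present = "epo:sign_A",
                                signs_absent = "epo:sign_A"),
               "both present and absent")

  add_image(s, image_annotation("i1", "epo:echographic_view_i",
                                signs_present = "epo:sign_A"))
  expect_error(
    add_image(s, image_annotation("i1", "epo:echographic_view_j")),
    "duplicate image_id")
})

test_that("derived sets track annotation unions; presence beats absence", {
  kb <- demo_kb()
  signs <- kb_entities(kb, "sign")$iri
  views <- kb_entities(kb, "echographic_view")$iri
  for (seed in 1:10) {
    set.seed(seed)
    s <- new_session(kb, "prop")
    present_all <- character(); absent_all <- character(); views_all <- character()
    for (k in seq_len(sample(1:6, 1))) {
      pr <- sample(signs, sample(0:3, 1))
      ab <- sample(setdiff(signs, pr), sample(0:3, 1))
      v <- sample(views, 1)
      add_image(s, image_annotation(sprintf("img%d", k), v,
                                    signs_present = pr, signs_absent = ab))
      present_all <- union(present_all, pr)
      absent_all <- union(absent_all, ab)
      views_all <- union(views_all, v)
    }
    expect_setequal(identified_signs(s), present_all)
    expect_setequal(absent_signs(s), setdiff(absent_all, present_all))
    expect_setequal(completed_views(s), views_all)
  }
})

test_that("guidance delegates to the reasoner on the session's derived sets", {
  s <- new_session(fig5_kb(), "c")
  add_image(s, image_annotation("i1", "epo:echographic_view_i",
                                signs_present = "epo:sign_A"))
  g <- next_guidance(s)
  direct <- personalized_protocol(fig5_kb(), identified_signs(s),
                                  completed_views(s), absent_signs(s))
  expect_identical(unclass(g), unclass(direct))
  expect_setequal(vapply(g, `[[`, "", "view"),
                  c("epo:echographic_view_j", "epo:echographic_view_k"))

  # marking all pending signs absent empties the guidance
  add_image(s, image_annotation("i2", "epo:echographic_view_j",
                                signs_absent = c("epo:sign_B", "epo:sign_C", "epo:sign_D")))
  expect_length(next_guidance(s), 0L)
})

test_that("the guided loop shrinks the pending set and terminates", {
  s <- new_session(demo_kb(), "loop")
  add_image(s, image_annotation("seed", "epo:uterus_sagittal_view",
                                signs_present = "epo:empty_uterine_cavity"))
  n_signs <- nrow(kb_entities(demo_kb(), "sign"))
  prev <- length(pending_signs(demo_kb(), identified_signs(s), absent_signs(s)))
  it <- 0L
  repeat {
    g <- next_guidance(s)
    if (length(g) == 0L) break
    it <- it + 1L
    expect_lte(it, n_signs)
    top <- g[[1L]]
    add_image(s, image_annotation(sprintf("g%d", it), top$view,
                                  signs_absent = top$sought_signs))
    cur <- length(pending_signs(demo_kb(), identified_signs(s), absent_signs(s)))
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("finalize produces a faithful, immutable report", {
  s <- new_session(fig5_kb(), "case_9")
  add_image(s, image_annotation("i1", "epo:echographic_view_i",
                                signs_present = "epo:sign_A"))
  expect_error(finalize_session(s, "op1", "assisted", diagnosis("intrauterine"), -1),
               "nonnegative")
  rep <- finalize_session(s, "op1", "assisted", diagnosis("ectopic", "tubal"), 12.5)
  expect_s3_class(rep, "scan_report")
  expect_equal(rep$image_ids, "i1")
  expect_equal(rep$image_count, 1L)
  expect_false(rep$protocol_complete) # views j/k still pending
  expect_error(finalize_session(s, "op1", "assisted", diagnosis("intrauterine"), 1),
               "already finalized")
  expect_error(add_image(s, image_annotation("i2", "epo:echographic_view_j")),
               "already finalized")

  # an immediate finalize with no images is protocol-complete on empty evidence
  s0 <- new_session(fig5_kb(), "case_0")
  rep0 <- finalize_session(s0, "op1", "nonassisted", diagnosis("pregnancy_of_unknown_location"), 0)
  expect_equal(rep0$image_count, 0L)
  expect_true(rep0$protocol_complete)
})

test_that("after k valid adds an immediate finalize reports k images", {
  kb <- demo_kb()
  views <- kb_entities(kb, "echographic_view")$iri
  for (k in c(1L, 3L, 6L)) {
    s <- new_session(kb, paste0("count", k))
    for (i in seq_len(k))
      add_image(s, image_annotation(sprintf("im%d", i), views[(i %% length(views)) + 1L]))
    rep <- finalize_session(s, "op", "assisted", diagnosis("intrauterine"), 5)
    expect_equal(rep$image_count, k)
  }
})

test_that("reports and sessions round-trip through JSON losslessly", {
  s <- new_session(fig5_kb(), "case_7")
  add_image(s, image_annotation("i1", "epo:echographic_view_i",
                                signs_present = "epo:sign_A",
                                signs_absent = "epo:sign_B"))
  js <- session_to_json(s)
  s2 <- session_from_json(js)
  expect_identical(identified_signs(s2), identified_signs(s))
  expect_identical(absent_signs(s2), absent_signs(s))
  expect_identical(s2$kb$triples, s$kb$triples)

  rep <- finalize_session(s, "op2", "nonassisted", diagnosis("ectopic", "tubal"), 8)
  rep2 <- report_from_json(report_to_json(rep))
  expect_equal(rep2[names(rep2) != "conclusion"], rep[names(rep) != "conclusion"],
               ignore_attr = TRUE)
  expect_equal(rep2$conclusion$location_class, "ectopic")
  expect_equal(rep2$conclusion$ectopic_site, "tubal")
})

test_that("diagnosis statements enforce the site constraint", {
  expect_error(diagnosis("intrauterine", "tubal"), "ectopic")
  expect_error(diagnosis("pregnancy_of_unknown_location", "tubal"), "ectopic")
  d <- diagnosis("ectopic", "tubal")
  expect_equal(format(d), "ectopic (tubal)")
  expect_null(diagnosis("intrauterine")$ectopic_site)
})
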