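test_that("the four reasoning steps reproduce the toy-ontology trace", {
  kb <- fig5_kb()
  expect_identical(disorders_for(kb, "epo:sign_A"),
                   c("epo:disorder_1", "epo:disorder_2"))
  expect_identical(signs_of(kb, c("epo:disorder_1", "epo:disorder_2")),
                   c("epo:sign_A", "epo:sign_B", "epo:sign_C", "epo:sign_D"))
  expect_identical(pending_signs(kb, "epo:sign_A"),
                   c("epo:sign_B", "epo:sign_C", "epo:sign_D"))
  expect_identical(views_for(kb, c("epo:sign_B", "epo:sign_C", "epo:sign_D")),
                   c("epo:echographic_view_j", "epo:echographic_view_k"))

  proto <- personalized_protocol(kb, "epo:sign_A")
  expect_length(proto, 2L)
  expect_setequal(vapply(proto, `[[`, "", "view"),
                  c("epo:echographic_view_j", "epo:echographic_view_k"))
  expect_setequal(unlist(lapply(proto, `[[`, "sought_signs")),
                  c("epo:sign_B", "epo:sign_C", "epo:sign_D"))
  expect_equal(vapply(proto, `[[`, 1L, "rank"), 1:2)
})

test_that("empty inputs yield empty outputs", {
  kb <- fig5_kb()
  expect_identical(disorders_for(kb, character()), character())
  expect_identical(signs_of(kb, character()), character())
  expect_identical(views_for(kb, character()), character())
  expect_length(personalized_protocol(kb, character()), 0L)
  expect_equal(nrow(differential(kb, character())), 0L)
  # identifying every associated sign leaves nothing pending
  expect_identical(
    pending_signs(kb, c("epo:sign_A", "epo:sign_B", "epo:sign_C", "epo:sign_D")),
    character())
})

test_that("unknown entities are rejected by name", {
  kb <- fig5_kb()
  expect_error(disorders_for(kb, "epo:nope"), "unknown sign: epo:nope")
  expect_error(signs_of(kb, "epo:sign_A"), "unknown disorder")
  expect_error(views_for(kb, "epo:disorder_1"), "unknown sign")
  expect_error(personalized_protocol(kb, "epo:sign_A", completed_views = "epo:sign_B"),
               "unknown echographic_view")
})

test_that("every operation equals its brute-force scan on random stores", {
  for (seed in 1:50) {
    kb <- random_kb(seed)
    identified <- random_sign_subset(kb, seed + 5000)
    expect_identical(disorders_for(kb, identified), brute_disorders_for(kb, identified))
    ds <- disorders_for(kb, identified)
    expect_identical(signs_of(kb, ds), brute_signs_of(kb, ds))
    expect_identical(pending_signs(kb, identified), brute_pending(kb, identified))
    expect_identical(views_for(kb, identified), brute_views_for(kb, identified))

    # protocol composition: item set equals the composed scans
    proto <- personalized_protocol(kb, identified)
    pend <- brute_pending(kb, identified)
    expect_setequal(vapply(proto, `[[`, "", "view"), brute_views_for(kb, pend))
    expect_setequal(c(character(), unlist(lapply(proto, `[[`, "sought_signs"))),
                    pend)
    for (it in proto)
      expect_setequal(it$sought_signs,
                      intersect(pend, brute_match(kb, p = "epo:requires_view",
                                                  o = it$view)$subject))

    # differential tallies equal the brute-force count
    dd <- differential(kb, identified)
    oracle <- brute_differential(kb, identified)
    expect_setequal(dd$disorder, c(character(), names(oracle)))
    for (i in seq_len(nrow(dd))) {
      expect_equal(dd$support[i], unname(oracle[[dd$disorder[i]]]["support"]))
      expect_equal(dd$total_signs[i], unname(oracle[[dd$disorder[i]]]["total"]))
    }
  }
})

test_that("protocol items are ordered most-informative-first with stated tie-breaks", {
  for (seed in 1:20) {
    kb <- random_kb(seed)
    proto <- personalized_protocol(kb, random_sign_subset(kb, seed + 7000))
    if (length(proto) < 2L) next
    ents <- kb_entities(kb)
    for (i in seq_len(length(proto) - 1L)) {
      a <- proto[[i]]; b <- proto[[i + 1L]]
      la <- ents$label[match(a$view, ents$iri)]
      lb <- ents$label[match(b$view, ents$iri)]
      expect_true(
        length(a$sought_signs) > length(b$sought_signs) ||
          (length(a$sought_signs) == length(b$sought_signs) &&
             (la < lb || (la == lb && a$view <= b$view))))
    }
    expect_equal(vapply(proto, `[[`, 1L, "rank"), seq_along(proto))
  }
})

test_that("adding an identified sign never removes a suggested disorder", {
  for (seed in 1:15) {
    kb <- random_kb(seed)
    signs <- kb_entities(kb, "sign")$iri
    set.seed(seed + 9000)
    base <- sample(signs, sample(0:(length(signs) - 1L), 1))
    extra <- sample(setdiff(signs, base), 1)
    expect_true(all(disorders_for(kb, base) %in% disorders_for(kb, c(base, extra))))
  }
})

test_that("protocols are sound: no completed view, no already-identified sign", {
  for (seed in 1:15) {
    kb <- random_kb(seed)
    identified <- random_sign_subset(kb, seed + 11000)
    views <- kb_entities(kb, "echographic_view")$iri
    set.seed(seed + 13000)
    done <- sample(views, sample(0:length(views), 1))
    proto <- personalized_protocol(kb, identified, completed_views = done)
    for (it in proto) {
      expect_false(it$view %in% done)
      expect_length(intersect(it$sought_signs, identified), 0L)
      # every sought sign indeed requires the item's view
      expect_true(all(it$view %in% brute_views_for(kb, it$sought_signs)))
    }
  }
})

test_that("assessing each protocol step's signs terminates the guidance loop", {
  for (seed in 1:10) {
    kb <- random_kb(seed)
    signs <- kb_entities(kb, "sign")$iri
    set.seed(seed + 17000)
    identified <- sample(signs, 1)
    absent <- character()
    n_iter <- 0L
    repeat {
      proto <- personalized_protocol(kb, identified, absent_signs = absent)
      if (length(proto) == 0L) break
      absent <- c(absent, proto[[1L]]$sought_signs) # assess them all absent
      n_iter <- n_iter + 1L
      expect_lte(n_iter, length(signs))
    }
    expect_lte(n_iter, length(signs))
  }
})

test_that("differential entries for a single shared sign have unit support", {
  dd <- differential(fig5_kb(), "epo:sign_A")
  expect_setequal(dd$disorder, c("epo:disorder_1", "epo:disorder_2"))
  expect_equal(dd$support, c(1L, 1L))
  expect_equal(dd$completeness, dd$support / dd$total_signs)
  # ordering: equal support resolved by descending completeness
  expect_true(all(diff(dd$support) <= 0))
})
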