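test_that("the bundled core module loads with its defined concepts", {
  mod <- load_module(file.path(fixture_dir(), "core.onto"))
  expect_s3_class(mod, "onto_module")
  expect_equal(mod$name, "core")
  lab <- mod$labels
  expect_true("field of exhaustion" %in% lab$text[lab$kind == "pref" & lab$lang == "en"])
  expect_equal(nrow(mod$defined), 7L)
  # defined restrictions all resolve inside core
  expect_equal(nrow(pending_refs(mod)), 0L)
})

test_that("an empty module file loads as a valid empty module", {
  f <- write_utf8("MODULE\tempty", tempfile(fileext = ".onto"))
  mod <- load_module(f)
  expect_equal(nrow(mod$concepts), 0L)
  expect_equal(nrow(mod$defined), 0L)
  expect_equal(nrow(pending_refs(mod)), 0L)
})

test_that("cross-module references are pending at load and resolve at consolidation", {
  a <- write_utf8(c("MODULE\ta", "PROPERTY\tp:r", "CONCEPT\ta:filler",
                    "DEFINED\ta:D", "ASSERT\tp:r\ta:filler"),
                  tempfile(fileext = ".onto"))
  b <- write_utf8(c("MODULE\tb", "IMPORT\ta", "CONCEPT\tb:x",
                    "ASSERT\tp:r\ta:filler"),
                  tempfile(fileext = ".onto"))
  mb <- load_module(b)
  pend <- pending_refs(mb)
  expect_equal(sort(pend$ref), c("a:filler", "p:r"))   # recorded, not dropped
  ont <- consolidate(list(load_module(a), mb))
  expect_equal(nrow(check_resolution(ont)), 0L)        # resolved after merge
})

test_that("module-level validation rejects malformed input", {
  dup <- write_utf8(c("MODULE\tm", "CONCEPT\tx", "CONCEPT\tx"),
                    tempfile(fileext = ".onto"))
  expect_error(load_module(dup), "duplicate iri")
  multi <- write_utf8(c("MODULE\tm", "PROPERTY\tp", "CONCEPT\tf", "CONCEPT\tg",
                        "DEFINED\tD", "ASSERT\tp\tf", "ASSERT\tp\tg"),
                      tempfile(fileext = ".onto"))
  expect_error(load_module(multi), "multiple restrictions")
  unknown <- write_utf8(c("MODULE\tm", "FROB\tx"), tempfile(fileext = ".onto"))
  expect_error(load_module(unknown), "unknown record")
  expect_error(load_module(tempfile()), "no such file")
})

test_that("labels without a language tag default to fr", {
  f <- write_utf8(c("MODULE\tm", "CONCEPT\tx", "LABEL\tpref\tchose"),
                  tempfile(fileext = ".onto"))
  mod <- load_module(f)
  expect_equal(mod$labels$lang, "fr")
  expect_equal(mod$labels$text, "chose")
})

test_that("consolidation conserves per-module counts and rejects collisions and cycles", {
  mods <- load_fixture_modules()
  ont <- consolidate(mods)
  expect_equal(nrow(ont$concepts) + nrow(ont$defined),
               sum(vapply(mods, function(m) nrow(m$concepts) + nrow(m$defined), 0L)))
  # the consolidation module contributes nothing
  cons <- mods[[which(vapply(mods, `[[`, "", "name") == "consolidation")]]
  expect_equal(nrow(cons$concepts) + nrow(cons$defined), 0L)

  met <- ontology_metrics(ont)
  manifest <- jsonlite::read_json(file.path(fixture_dir(), "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(met$n_classes, manifest$n_classes)
  expect_equal(met$n_defined, manifest$n_defined)
  tot <- met[met$module == "total", ]
  expect_equal(tot$n_classes, sum(met$n_classes[met$module != "total"]))
  expect_equal(tot$n_defined, sum(met$n_defined[met$module != "total"]))

  # iri collision across modules
  clash <- load_module(write_utf8(c("MODULE\tother", "CONCEPT\tsoc:Famille"),
                                  tempfile(fileext = ".onto")))
  expect_error(consolidate(c(mods, list(clash))), "collision")
  # unresolved reference
  dangling <- load_module(write_utf8(c("MODULE\tdang", "CONCEPT\tz", "PARENT\tnowhere"),
                                     tempfile(fileext = ".onto")))
  expect_error(consolidate(list(dangling)), "unresolved")
  # import cycle
  m1 <- onto_module("m1", imports = "m2")
  m2 <- onto_module("m2", imports = "m1")
  expect_error(consolidate(list(m1, m2)), "cycle")
})

test_that("consolidation is invariant under module permutation", {
  mods <- load_fixture_modules()
  ont1 <- consolidate(mods)
  set.seed(42)
  for (k in 1:3) {
    ont2 <- consolidate(sample(mods))
    expect_identical(ont1$concepts, ont2$concepts)
    expect_identical(ont1$labels, ont2$labels)
    expect_identical(ont1$parents, ont2$parents)
    expect_identical(ont1$assertions, ont2$assertions)
    expect_identical(ont1$defined, ont2$defined)
  }
})

test_that("metrics of an empty ontology are all zero", {
  ont <- consolidate(list(onto_module("void")))
  met <- ontology_metrics(ont)
  expect_true(all(met[c("n_classes", "n_properties", "n_defined")] == 0L))
})

test_that("plaintext and RDF/XML round trips reproduce the graph", {
  ont <- fixture_ontology(reasoned = FALSE)
  for (fmt in c("plaintext", "rdfxml")) {
    f <- tempfile(fileext = if (fmt == "rdfxml") ".owl" else ".onto")
    if (fmt == "plaintext") write_ontology(ont, f) else write_ontology_rdfxml(ont, f)
    back <- consolidate(list(load_module(f, format = fmt)))
    expect_equal(sort(back$concepts$iri), sort(ont$concepts$iri), info = fmt)
    expect_equal(sort(back$defined$iri), sort(ont$defined$iri), info = fmt)
    expect_identical(back$labels[c("iri", "kind", "lang", "text")],
                     ont$labels[c("iri", "kind", "lang", "text")], info = fmt)
    expect_identical(edge_key(back$parents), edge_key(ont$parents), info = fmt)
    expect_identical(order_df(back$assertions, c("iri", "property", "filler")),
                     order_df(ont$assertions, c("iri", "property", "filler")),
                     info = fmt)
  }
})

test_that("subclass cycles among named concepts are rejected", {
  f <- write_utf8(c("MODULE\tm", "CONCEPT\ta", "PARENT\tb", "CONCEPT\tb", "PARENT\ta"),
                  tempfile(fileext = ".onto"))
  expect_error(consolidate(list(load_module(f))), "cycle")
})
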