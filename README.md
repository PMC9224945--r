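# GenomicVault

Genomic data is privacy-critical: a leaked genome exposes not just one
person but their relatives, and most mainstream genomic file formats carry
no protection mechanism of their own. GenomicVault is an R toolkit for
storing genomic payloads inside a *protected hierarchical container* and
controlling every access to them with machine-evaluable privacy rules. It
is aimed at engineers and data stewards building secure genomic archives,
and at researchers who want a desk-scale, fully scriptable model of how
container-level protection, attribute-based access control and envelope
encryption fit together.

The package implements four connected layers:

1. **Hierarchical container** — an MPEG-G-style box hierarchy (File →
   Dataset Group → Dataset → Access Unit → Block) mirrored on the file
   system: groups live in `dg_X` directories, datasets in `dt_X`, access
   units in `au_X`, payloads in `block_X` files; headers are `flhd`/`dghd`/
   `dthd`/`auhd`, metadata `dgmd`/`dtmd`, protection `dgpr`/`dtpr`/`aupr`.
   `packContainer()` folds the tree deterministically into a single
   length-prefixed binary box stream and `unpackContainer()` restores it.
2. **Privacy rules** — an XACML 3.0 subset (Policy/Rule/Target/Condition,
   Requests, deny-overrides / permit-overrides / first-applicable
   combining). A rule states *who* (role), *what action* (an API method
   such as `GetDataBySimpleFilter`) and *under which conditions* (situation,
   read count ≤ cap, alignment flags, and a genomic region
   `[start, end] ⊆ [lo, hi]` with both extremes included) access is
   granted. Rules are stored as XML inside the protection box of the
   dataset group or dataset they govern — the protected resource is
   implicit, never named in the rule.
3. **Hierarchical authorization** — two algorithms connect the rule levels:
   a dataset request is first checked against dataset rules, and only if
   they do not grant is the *same request* evaluated against the enclosing
   group (a group-level grant is delegated downward and annotated with
   `granted_by_dataset_group = true`); a group-wide request, once granted,
   is re-checked dataset by dataset so that any dataset whose own rules do
   not grant is blocked. A dataset-level Permit is never overridden by
   group rules.
4. **Cryptography** — selective authenticated encryption of individual
   blocks or metadata files (AES-256-CTR + HMAC-SHA256 encrypt-then-MAC),
   detached Ed25519 signatures, passphrase key-wrapping, and a
   Crypt4GH-style envelope: per-recipient X25519 header packets discovered
   by trial decryption, 65,536-byte authenticated segments, and byte-range
   decryption that touches only the segments overlapping the requested
   `[P, Q)`.

EGA (Study/Assembly) and NCBI (BioProject/BioSample) study metadata map
onto the container's metadata records (`mapFromEga()`, `mapFromNcbi()` —
NCBI has no Abstract, so that field stays empty), with an extension
mechanism for additional attributes (`StudyDesign`, `BodySite`,
`AnalyteType`, `IsTumor`). An in-memory metadata index supports substring
search in which every hit is filtered through metadata-read authorization
before it is shown.

## Worked example

The package ships a reference privacy rule: the role *practitioner* may run
`GetDataBySimpleFilter` under an emergency situation, for a read count of at
most 5000, without multiple alignments, on reference sequence 4, for a
region inside positions 40,810,027–41,216,714 (both extremes included) — the
kind of rule used to guard genome regions linked to Alzheimer's disease
predisposition.

```r
library(GenomicVault)

wx <- buildWorkedExample()
evaluatePolicy(wx$policy, wx$request)        # a researcher's request
#> Decision: NotApplicable
evaluatePolicy(wx$policy, workedExampleMatchingRequest())
#> Decision: Permit (rules: alzheimer-region-access )
```

The first request carries the role `researcher`, which the rule's target
does not match, so nothing applies and the caller treats the decision as
not granted; the fully matching practitioner request is permitted. The
hierarchical layer behaves the same way through a container:

```r
c <- generateFixture(fixtureSpec(seed = 7, policyTemplate = "worked-example"),
                     file.path(tempdir(), "vault"))
authorizeDataset(c, 0, 0, workedExampleMatchingRequest())
#> AuthzResult: Permit granted_by = dataset
authorizeDataset(c, 0, 0, wx$request)
#> AuthzResult: Deny granted_by = none
```

Selective encryption leaves every byte outside the chosen target untouched:

```r
key <- contentKeygen()
plaintext <- as.raw(readBlock(c, 0, 0, 0, 0))
encryptTarget(c, "dg_0/dt_0/au_0/block_0", key)
identical(as.raw(decryptTarget(c, "dg_0/dt_0/au_0/block_0", key)), plaintext)
#> [1] TRUE
decryptTarget(c, "dg_0/dt_0/au_0/block_0", contentKeygen())
#> Error: authentication tag mismatch
```

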