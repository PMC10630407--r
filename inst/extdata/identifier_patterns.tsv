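scheme	match_mode	pattern
DOI	search	^10.\d{4,9}/[-._;()/:a-zA-Z0-9]+$
ORCID	search	^\d{4}-\d{4}-\d{4}-(\d{3}X|\d{4})
ISNI_presentation	full_match	[0-9]{4} [0-9]{4} [0-9]{4} [0-9]{3}[0-9X]
ISNI_compact	full_match	[0-9]{15}[0-9X]
GRID	full_match	grid\.\d{4,6}\.[0-9a-f]{1,2}
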