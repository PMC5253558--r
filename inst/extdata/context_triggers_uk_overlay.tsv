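# British-English overlay for the base ConText trigger table. OFF by default;
# load with load_triggers(overlay = TRUE). Kept separate so the base table stays
# reproducible against the published term lists.
phrase	property	direction	action
nil	negation	forward	set
nil of note	negation	forward	set
denies any	negation	forward	set
denied any	negation	forward	set
no evidence	negation	forward	set
not elicited	negation	backward	set
nad	negation	backward	set
settled with no	negation	forward	set
mum	experiencer	forward	set
dad	experiencer	forward	set
carer	experiencer	forward	set
keyworker	experiencer	forward	set
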