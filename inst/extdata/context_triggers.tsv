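# ConText-style trigger table (base edition).
# Initialised from the published ConText/NegEx term lists (negation, experiencer,
# temporality), plus screening-verb hypothetical phrases common in mental-state
# documentation. Phrases are token sequences; a trailing * on a token means
# prefix match. direction: forward = scope runs from the trigger to the end of
# the sentence (cut at a termination term); backward = scope runs from the
# sentence start (or the nearest preceding termination term) to the trigger.
# action "set" asserts the property over the scope; "terminate" cuts scopes of
# that property; pseudo_negation rows block negation triggers inside their span.
phrase	property	direction	action
no	negation	forward	set
not	negation	forward	set
without	negation	forward	set
denies	negation	forward	set
denied	negation	forward	set
deny	negation	forward	set
denying	negation	forward	set
never	negation	forward	set
no evidence of	negation	forward	set
no sign of	negation	forward	set
no signs of	negation	forward	set
no suggestion of	negation	forward	set
absence of	negation	forward	set
free of	negation	forward	set
negative for	negation	forward	set
cannot	negation	forward	set
fails to	negation	forward	set
failed to	negation	forward	set
resolution of	negation	forward	set
unremarkable for	negation	forward	set
unlikely	negation	backward	set
not present	negation	backward	set
was ruled out	negation	backward	set
were ruled out	negation	backward	set
absent	negation	backward	set
not demonstrated	negation	backward	set
no increase	pseudo_negation	forward	set
no change	pseudo_negation	forward	set
no further	pseudo_negation	forward	set
not only	pseudo_negation	forward	set
not necessarily	pseudo_negation	forward	set
not certain if	pseudo_negation	forward	set
not certain whether	pseudo_negation	forward	set
gradually	pseudo_negation	forward	set
not cause	pseudo_negation	forward	set
mother*	experiencer	forward	set
father*	experiencer	forward	set
brother	experiencer	forward	set
sister	experiencer	forward	set
wife	experiencer	forward	set
husband	experiencer	forward	set
partner	experiencer	forward	set
son	experiencer	forward	set
daughter	experiencer	forward	set
aunt	experiencer	forward	set
uncle	experiencer	forward	set
grandmother	experiencer	forward	set
grandfather	experiencer	forward	set
family	experiencer	forward	set
family history	experiencer	forward	set
neighbour	experiencer	forward	set
flatmate	experiencer	forward	set
history of	historical	forward	set
past history of	historical	forward	set
previous	historical	forward	set
previously	historical	forward	set
in the past	historical	forward	set
years ago	historical	backward	set
months ago	historical	backward	set
if	hypothetical	forward	set
should	hypothetical	forward	set
in case	hypothetical	forward	set
as needed	hypothetical	forward	set
returns	hypothetical	forward	set
come back	hypothetical	forward	set
rule out	hypothetical	forward	set
examined for	hypothetical	forward	set
examined the patient for	hypothetical	forward	set
examined her for	hypothetical	forward	set
examined him for	hypothetical	forward	set
screen for	hypothetical	forward	set
screened for	hypothetical	forward	set
screening for	hypothetical	forward	set
assess for	hypothetical	forward	set
assessed for	hypothetical	forward	set
assessing for	hypothetical	forward	set
monitor for	hypothetical	forward	set
monitoring for	hypothetical	forward	set
check for	hypothetical	forward	set
checked for	hypothetical	forward	set
evaluate for	hypothetical	forward	set
evaluated for	hypothetical	forward	set
watch for	hypothetical	forward	set
but	negation	both	terminate
however	negation	both	terminate
although	negation	both	terminate
apart from	negation	both	terminate
aside from	negation	both	terminate
except	negation	both	terminate
but	experiencer	both	terminate
however	experiencer	both	terminate
although	experiencer	both	terminate
but	historical	both	terminate
however	historical	both	terminate
although	historical	both	terminate
but	hypothetical	both	terminate
however	hypothetical	both	terminate
although	hypothetical	both	terminate
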