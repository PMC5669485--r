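# Interaction keyword lexicon: one lowercase lemma per line.
# Inflected forms (binds, binding, interaction, ...) are matched through
# the lemmatizer. User-overridable via read_lexicon(path).
abolish
acetylate
activate
affect
anchor
antagonize
associate
attenuate
bind
block
catalyze
cleave
coaggregate
coassemble
cocrystallize
coelute
cofractionate
coimmunoprecipitate
colocalize
copurify
cosediment
complex
connect
contact
cooperate
couple
crosslink
degrade
dephosphorylate
destabilize
dimerize
disrupt
dock
downregulate
enhance
heterodimerize
hydrolyze
impair
induce
influence
inhibit
interact
link
mediate
methylate
modulate
oligomerize
phosphorylate
prevent
promote
recruit
regulate
repress
sequester
stabilize
stimulate
suppress
synergize
target
tether
transactivate
transduce
translocate
trigger
ubiquitinate
upregulate
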