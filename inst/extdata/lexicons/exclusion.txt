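but
else
other
others
otherwise
except
without
exclud*
rather
whether
either
versus
instead
unless
differ*
distinct*
separate*
unique*
apart
aside
besides
alternative*
contrast*
oppos*
unlike
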