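and
but
or
if
because
when
while
although
though
since
unless
until
whereas
so
then
also
plus
nor
whenever
wherever
once
till
than
as
how
whereby
besides
moreover
furthermore
meanwhile
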