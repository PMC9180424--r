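me
you
he
she
it
we
they
i
a
an
the
and
or
of
to
in
is
are
was
be
this
that
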