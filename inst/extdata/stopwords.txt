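a
an
and
or
but
if
of
in
on
at
to
for
with
is
are
was
were
be
been
being
this
that
these
those
it
its
as
by
from
will
would
could
should
have
has
had
do
does
did
not
no
so
than
then
there
here
about
into
over
under
again
very
just
now
more
most
some
such
only
own
same
too
can
may
might
must
shall
we
our
ours
you
your
yours
they
their
theirs
he
she
his
her
hers
i
me
my
mine
us
them
what
which
who
whom
when
where
why
how
all
any
both
each
few
other
because
while
during
before
after
above
below
up
down
out
off
once
the
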